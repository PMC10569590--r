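# Independent oracles used across test files.

# Brute-force DBSCAN oracle: O(n^2) reachability by repeated scans of the
# full distance matrix (no union-find, no frontier bookkeeping), with the
# same core/border semantics as standard DBSCAN.
brute_force_dbscan <- function(x, eps, min_pts = 2) {
  x <- rbind(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d2 <- as.matrix(dist(x))^2
  nb <- d2 <= eps^2
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0) next
    cl <- cl + 1
    member <- rep(FALSE, n)
    member[i] <- TRUE
    repeat {
      grew <- FALSE
      for (j in which(member & core)) {
        add <- nb[j, ] & !member
        if (any(add)) {
          member <- member | add
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    labels[member] <- cl
  }
  labels
}

# partitions equal up to relabelling (0 = noise must match exactly)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  keep <- a != 0
  if (!any(keep)) return(TRUE)
  key_a <- match(a[keep], unique(a[keep]))
  key_b <- match(b[keep], unique(b[keep]))
  identical(key_a, key_b)
}

# small-footprint configuration for pipeline tests
small_config <- function(...) {
  cfg <- default_config()
  cfg$primaries <- 2e4
  cfg$nano_primaries <- 400
  cfg$n_nucleosomes <- 2000
  cfg$configurations <- c("water_column", "benthic_mixture_frustule")
  utils::modifyList(cfg, list(...))
}
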