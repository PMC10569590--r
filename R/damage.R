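#' DBSCAN strand-break scoring parameters
#'
#' The damage scorer follows the clustering convention of track-structure
#' DNA-damage codes: every energy-transfer point can be a single-strand
#' break (SSB) candidate with probability `s_point_prob` (the chance that
#' the point lies in a DNA-sensitive region — helix plus a virtual aura
#' lumping direct and indirect damage) multiplied by a damage probability
#' that rises linearly from 0 at `ramp_min` (5 eV) to 1 at `ramp_max`
#' (37.5 eV) of deposited energy. SSBs are clustered with DBSCAN using
#' neighbourhood radius `eps` (3.3 nm, about 10 base pairs); any cluster
#' holding at least `min_ssb_for_dsb` SSBs counts as one double-strand
#' break (DSB).
#'
#' @param eps DBSCAN neighbourhood radius, nm
#' @param min_ssb_for_dsb minimum SSBs within a cluster to form a DSB
#' @param s_point_prob sensitive-point probability, in (0, 1]
#' @param ramp_min,ramp_max linear damage-probability ramp bounds, eV
#' @return object of class `dbscan_params`
#' @export
dbscan_params <- function(eps = 3.3, min_ssb_for_dsb = 2,
                          s_point_prob = 0.08, ramp_min = 5,
                          ramp_max = 37.5) {
  stopifnot(eps > 0, min_ssb_for_dsb >= 2,
            s_point_prob >= 0, s_point_prob <= 1, ramp_min < ramp_max)
  structure(list(eps = eps, min_ssb_for_dsb = min_ssb_for_dsb,
                 s_point_prob = s_point_prob, ramp_min = ramp_min,
                 ramp_max = ramp_max),
            class = "dbscan_params")
}

#' SSB damage probability as a function of deposited energy
#'
#' Zero at or below `ramp_min` (5 eV), rising linearly to 1 at `ramp_max`
#' (37.5 eV), and 1 above.
#'
#' @param edep deposited energy, eV (vectorised, >= 0)
#' @param params a [dbscan_params()]
#' @return damage probability in [0, 1]
#' @examples
#' ssb_probability(c(5, 21.25, 37.5))  # 0, 0.5, 1
#' @export
ssb_probability <- function(edep, params = dbscan_params()) {
  if (any(edep < 0)) stop("deposited energy must be >= 0")
  pmin(pmax((edep - params$ramp_min) / (params$ramp_max - params$ramp_min),
            0), 1)
}

#' Select SSB candidate points from energy-transfer points
#'
#' Each point is kept independently with probability
#' `s_point_prob * ssb_probability(energy_ev)`, so the expected SSB count is
#' exactly linear in `s_point_prob`. Uses the current RNG state.
#'
#' @param points data.frame with at least `x`, `y`, `z`, `energy_ev`
#' @param params a [dbscan_params()]
#' @param u optional pre-drawn uniforms (length `nrow(points)`), used by the
#'   calibration sweep to make selections nested across `s_point_prob`
#'   values
#' @return the selected subset of `points`
#' @export
select_ssb_points <- function(points, params = dbscan_params(), u = NULL) {
  if (nrow(points) == 0) return(points)
  if (is.null(u)) u <- stats::runif(nrow(points))
  keep <- u < params$s_point_prob * ssb_probability(points$energy_ev, params)
  points[keep, , drop = FALSE]
}

#' DBSCAN clustering of SSB points
#'
#' Standard DBSCAN on 3-D coordinates: a point is a core point if at least
#' `min_pts` points (itself included) lie within `eps`; clusters are the
#' connected components of core points under eps-reachability, with border
#' points attached to the cluster of a core neighbour; remaining points are
#' noise (label 0). With `min_pts = 2` every non-noise point is a core
#' point, so there is no border ambiguity.
#'
#' @param x n x 3 coordinate matrix (nm)
#' @param eps neighbourhood radius
#' @param min_pts minimum neighbourhood size (point itself included)
#' @return integer vector of cluster labels (0 = noise)
#' @export
dbscan_cluster <- function(x, eps, min_pts = 2) {
  x <- rbind(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d2 <- as.matrix(stats::dist(x))^2
  nb <- d2 <= eps^2          # neighbourhood incl. self
  sizes <- rowSums(nb)
  core <- sizes >= min_pts
  labels <- integer(n)
  cl <- 0
  for (i in seq_len(n)) {
    if (labels[i] != 0 || !core[i]) next
    cl <- cl + 1
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nbrs <- which(nb[frontier[1], ] & labels == 0)
      frontier <- frontier[-1]
      if (length(nbrs)) {
        labels[nbrs] <- cl
        frontier <- c(frontier, nbrs[core[nbrs]])
      }
    }
  }
  labels
}

#' Count DSBs among clustered SSBs
#'
#' One DSB per cluster containing at least `min_ssb` SSBs, regardless of
#' cluster size.
#'
#' @param labels cluster labels from [dbscan_cluster()] (0 = noise)
#' @param min_ssb minimum SSBs per DSB-qualifying cluster
#' @return number of DSBs
#' @export
count_dsb <- function(labels, min_ssb = 2) {
  labels <- labels[labels > 0]
  if (!length(labels)) return(0L)
  sum(table(labels) >= min_ssb)
}

#' Strand-break yield per Gray per megabase pair
#'
#' @param count number of breaks scored
#' @param nucleus_dose_gy dose to the nucleus over the same run, Gy (> 0)
#' @param genome_mbp genome size, Mbp (default 27)
#' @return yield in Gy^-1 Mbp^-1
#' @export
yields_per_gy_mbp <- function(count, nucleus_dose_gy, genome_mbp = 27) {
  if (any(nucleus_dose_gy <= 0)) stop("nucleus dose must be positive")
  count / nucleus_dose_gy / genome_mbp
}

#' Strand breaks per day of exposure
#'
#' Combines per-nuclide yields (per Gy per Mbp) with the per-nuclide
#' microorganism dose rates at the reference activities:
#' \deqn{breaks/day = \sum_n yield_n \times \dot D_n \times 24 \times 10^{-6}
#'   \times genome}
#' with dose rates in uGy/h.
#'
#' @param yields named numeric vector of per-nuclide yields
#'   (Gy^-1 Mbp^-1); names must match `dose_rates`
#' @param dose_rates named numeric vector of per-nuclide dose rates (uGy/h)
#' @param genome_mbp genome size, Mbp
#' @return breaks per day
#' @examples
#' per_day(c(rn222 = 0.08), c(rn222 = 2.8))   # ~1.45e-4 SSB/day
#' @export
per_day <- function(yields, dose_rates, genome_mbp = 27) {
  nm <- names(yields)
  if (is.null(nm) || !all(nm %in% names(dose_rates))) {
    stop("yields and dose_rates must share nuclide names")
  }
  sum(yields * dose_rates[nm] * 24e-6 * genome_mbp)
}

#' Sensitive-point probability calibration sweep
#'
#' Monoenergetic alphas are replayed as uniform random chords through the
#' nucleus ([monoenergetic_phase_space()]), transfer points are generated
#' once per track, and the DBSCAN scorer is applied for every requested
#' `s_point_prob` on the same point sets with nested selections (common
#' random numbers), which makes the DSB yield exactly monotone in
#' `s_point_prob` at fixed energy.
#'
#' @param energies alpha energies, MeV
#' @param s_point_probs sensitive-point probabilities to test
#' @param n_tracks chords per energy
#' @param geometry a [cell_geometry()]
#' @param ts a [ts_params()]
#' @param params baseline [dbscan_params()] (eps, ramp, minPts)
#' @param genome_mbp genome size, Mbp
#' @param seed optional integer seed
#' @param model a [range_energy_model()]
#' @return data.frame with columns `energy`, `s_point_prob`,
#'   `ssb_per_gy_mbp`, `dsb_per_gy_mbp`
#' @export
spointprob_sweep <- function(energies = c(2, 4, 6, 8, 10),
                             s_point_probs = c(0.08, 0.12, 0.16, 0.20),
                             n_tracks = 200, geometry = cell_geometry(),
                             ts = ts_params(), params = dbscan_params(),
                             genome_mbp = 27, seed = NULL,
                             model = default_range_model()) {
  if (!is.null(seed)) set.seed(seed)
  m_nuc <- .sphere_mass_kg(geometry$r_nucleus, 1.0)
  r_nm <- geometry$r_nucleus * 1000
  out <- list()
  for (e in energies) {
    phsp <- monoenergetic_phase_space(e, n_tracks, geometry)
    ssb <- stats::setNames(numeric(length(s_point_probs)),
                           as.character(s_point_probs))
    dsb <- ssb
    dose <- 0
    for (i in seq_len(n_tracks)) {
      p <- c(phsp$x_um[i], phsp$y_um[i], phsp$z_um[i]) * 1000
      u <- c(phsp$dx[i], phsp$dy[i], phsp$dz[i])
      b <- sum(p * u)
      chord <- max(-b + sqrt(max(b^2 - (sum(p^2) - r_nm^2), 0)), 0)
      pts <- generate_transfer_points(e, p, u, chord, ts, model)
      dose <- dose + sum(pts$energy_ev) * .EV_TO_J / m_nuc
      if (nrow(pts) == 0) next
      uu <- stats::runif(nrow(pts))
      for (s in s_point_probs) {
        pp <- dbscan_params(eps = params$eps,
                            min_ssb_for_dsb = params$min_ssb_for_dsb,
                            s_point_prob = s, ramp_min = params$ramp_min,
                            ramp_max = params$ramp_max)
        sel <- select_ssb_points(pts, pp, u = uu)
        key <- as.character(s)
        ssb[key] <- ssb[key] + nrow(sel)
        if (nrow(sel) >= 2) {
          lab <- dbscan_cluster(as.matrix(sel[, c("x", "y", "z")]),
                                pp$eps, pp$min_ssb_for_dsb)
          dsb[key] <- dsb[key] + count_dsb(lab, pp$min_ssb_for_dsb)
        }
      }
    }
    out[[length(out) + 1]] <- data.frame(
      energy = e, s_point_prob = s_point_probs,
      ssb_per_gy_mbp = yields_per_gy_mbp(unname(ssb), dose, genome_mbp),
      dsb_per_gy_mbp = yields_per_gy_mbp(unname(dsb), dose, genome_mbp))
  }
  do.call(rbind, out)
}
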