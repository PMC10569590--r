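#' Trace alpha particles through the layered sphere geometry
#'
#' Straight-line continuous-slowing-down transport: each track is a ray from
#' its emission point; intersections with the nucleus, microorganism, frustule
#' and environment spheres are computed analytically, each traversed segment
#' is converted to its water-equivalent length, and the energy deposited in a
#' region is the CSDA loss over that segment. Tracks terminate where the
#' residual energy reaches zero. Energy is conserved exactly: deposits over
#' all regions sum to the initial kinetic energy for contained tracks.
#'
#' @param energy emission energies in MeV (length n)
#' @param position n x 3 matrix of emission points (um); must lie outside the
#'   diatom (radius > microorganism + frustule)
#' @param direction n x 3 matrix of unit direction vectors
#' @param geometry a [cell_geometry()]
#' @param model a [range_energy_model()]
#' @return data.frame with one row per track: deposits per region (MeV;
#'   `dep_environment`, `dep_frustule`, `dep_microorganism` including the
#'   nucleus, `dep_nucleus`), entry flags and kinetic energies at the
#'   microorganism and nucleus surfaces, entry distances along the ray, and
#'   the geometric chord length inside the nucleus (`nucleus_chord`, um)
#' @export
trace_alpha <- function(energy, position, direction,
                        geometry = cell_geometry(),
                        model = default_range_model()) {
  position <- rbind(position)
  direction <- rbind(direction)
  n <- length(energy)
  stopifnot(nrow(position) == n, nrow(direction) == n)
  d2 <- rowSums(position^2)
  if (any(d2 < geometry$r_outer^2 * (1 - 1e-12))) {
    stop("emission points must lie outside the diatom (r > r_microorganism + frustule)")
  }
  b <- rowSums(position * direction)

  hit <- function(r) {
    disc <- b^2 - (d2 - r^2)
    ok <- disc > 0 & -b - sqrt(pmax(disc, 0)) > 0
    s <- sqrt(pmax(disc, 0))
    list(ok = ok, t1 = -b - s, t2 = -b + s)
  }
  ho <- hit(geometry$r_outer)
  hm <- hit(geometry$r_microorganism)
  hn <- hit(geometry$r_nucleus)
  hit_o <- ho$ok
  hit_m <- hit_o & hm$ok
  hit_n <- hit_m & hn$ok

  # collapse unhit inner boundaries onto the enclosing chord midpoint so the
  # corresponding segment lengths vanish
  t1o <- ifelse(hit_o, ho$t1, 0)
  t2o <- ifelse(hit_o, ho$t2, 0)
  mid_o <- (t1o + t2o) / 2
  t1m <- ifelse(hit_m, hm$t1, mid_o)
  t2m <- ifelse(hit_m, hm$t2, mid_o)
  mid_m <- (t1m + t2m) / 2
  t1n <- ifelse(hit_n, hn$t1, mid_m)
  t2n <- ifelse(hit_n, hn$t2, mid_m)

  f_env <- .linear_scaling(geometry$environment_material)
  f_fr <- .linear_scaling(geometry$frustule_material)

  w1 <- t1o * f_env                       # environment, inbound
  w2 <- w1 + (t1m - t1o) * f_fr          # frustule, inbound
  w3 <- w2 + (t1n - t1m)                 # microorganism water, inbound
  w4 <- w3 + (t2n - t1n)                 # nucleus
  w5 <- w4 + (t2m - t2n)                 # microorganism water, outbound
  w6 <- w5 + (t2o - t2m) * f_fr          # frustule, outbound

  r0 <- csda_range(energy, model)
  einv <- function(w) csda_energy(pmax(r0 - w, 0), model)
  e1 <- einv(w1); e2 <- einv(w2); e3 <- einv(w3)
  e4 <- einv(w4); e5 <- einv(w5); e6 <- einv(w6)

  dep_env <- ifelse(hit_o, (energy - e1) + e6, energy)
  dep_fr <- ifelse(hit_o, (e1 - e2) + (e5 - e6), 0)
  dep_mic <- ifelse(hit_o, e2 - e5, 0)
  dep_nuc <- ifelse(hit_o, e3 - e4, 0)

  entered_m <- hit_m & e2 > 0
  entered_n <- hit_n & e3 > 0

  data.frame(
    dep_environment = dep_env,
    dep_frustule = dep_fr,
    dep_microorganism = dep_mic,
    dep_nucleus = dep_nuc,
    entered_microorganism = entered_m,
    entered_nucleus = entered_n,
    energy_at_microorganism = ifelse(entered_m, e2, NA_real_),
    energy_at_nucleus = ifelse(entered_n, e3, NA_real_),
    t_microorganism = ifelse(entered_m, t1m, NA_real_),
    t_nucleus = ifelse(entered_n, t1n, NA_real_),
    nucleus_chord = ifelse(entered_n, t2n - t1n, NA_real_)
  )
}

#' Run the microdosimetric transport stage
#'
#' Simulates `n_primaries` alpha decays per nuclide present in the scenario
#' (Rn-222 for porosity > 0, Ra-226 for porosity < 100), scores the energy
#' deposited in each region, and records phase spaces at the microorganism
#' and nucleus surfaces. Primaries are processed in batches; the batch-to-
#' batch spread provides the statistical uncertainty of the region doses.
#'
#' With `toward_nucleus = TRUE` emissions are aimed into the nucleus cone
#' with matching statistical weights (see [sample_emission()]), which
#' populates the nucleus phase space efficiently for the nanodosimetric
#' stage; all reported per-primary quantities remain unbiased, but the
#' microorganism-surface phase space is then representative only of
#' nucleus-crossing tracks and is not recorded.
#'
#' @param scenario an [activity_scenario()]
#' @param n_primaries number of decays to simulate per nuclide
#' @param seed optional integer seed
#' @param n_batches number of batches for the uncertainty estimate
#' @param toward_nucleus logical, forced nucleus-aimed sampling
#' @param keep_microorganism_phase_space logical; keep per-entrant records at
#'   the microorganism surface (energies are always kept)
#' @param model a [range_energy_model()]
#' @param batch_rows maximum number of tracks held in memory at once
#' @return `microdose_result`: per-nuclide list with total deposits (MeV),
#'   absolute doses (Gy) and their relative SD, entrant counts and fractions,
#'   mean entry energies, and phase-space data.frames
#' @export
run_microdose <- function(scenario, n_primaries = 1e6, seed = NULL,
                          n_batches = 10, toward_nucleus = FALSE,
                          keep_microorganism_phase_space = !toward_nucleus,
                          model = default_range_model(),
                          batch_rows = 2e5) {
  stopifnot(inherits(scenario, "activity_scenario"), n_primaries >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- scenario$geometry
  spectra <- builtin_spectra()
  nuclides <- character(0)
  if (scenario$porosity > 0 && scenario$c_rn > 0) nuclides <- c(nuclides, "rn222")
  if (scenario$porosity < 100 && scenario$c_ra > 0) nuclides <- c(nuclides, "ra226")
  if (length(nuclides) == 0) {
    stop("scenario has no active source (zero concentrations)")
  }

  masses <- list(
    microorganism = .sphere_mass_kg(g$r_microorganism, 1.0),
    nucleus = .sphere_mass_kg(g$r_nucleus, 1.0),
    frustule = .shell_mass_kg(g$r_microorganism, g$r_outer,
                              g$frustule_material$density)
  )

  per_nuclide <- list()
  for (nuc in nuclides) {
    sp <- spectra[[nuc]]
    batch_id <- rep(seq_len(n_batches), length.out = n_primaries)
    dep_tot <- c(environment = 0, frustule = 0, microorganism = 0, nucleus = 0)
    batch_micro <- numeric(n_batches)
    n_entered_m <- 0; n_entered_n <- 0
    w_entered_m <- 0; w_entered_n <- 0
    sum_w <- 0
    e_micro <- list(); w_micro <- list()
    phsp_m <- list(); phsp_n <- list()
    done <- 0; chunk_i <- 0
    while (done < n_primaries) {
      m <- min(batch_rows, n_primaries - done)
      chunk_i <- chunk_i + 1
      e0 <- sample_decay(sp, m)
      em <- sample_emission(g, m, toward_nucleus = toward_nucleus)
      tr <- trace_alpha(e0, em$position, em$direction, g, model)
      w <- em$weight
      sum_w <- sum_w + sum(w)
      dep_tot <- dep_tot + c(sum(w * tr$dep_environment),
                             sum(w * tr$dep_frustule),
                             sum(w * tr$dep_microorganism),
                             sum(w * tr$dep_nucleus))
      bid <- batch_id[(done + 1):(done + m)]
      batch_micro <- batch_micro +
        as.numeric(rowsum(w * tr$dep_microorganism, bid,
                          reorder = TRUE)[paste(1:n_batches), 1] |>
                     (\(x) ifelse(is.na(x), 0, x))())
      im <- which(tr$entered_microorganism)
      iN <- which(tr$entered_nucleus)
      n_entered_m <- n_entered_m + length(im)
      n_entered_n <- n_entered_n + length(iN)
      w_entered_m <- w_entered_m + sum(w[im])
      w_entered_n <- w_entered_n + sum(w[iN])
      e_micro[[chunk_i]] <- tr$energy_at_microorganism[im]
      w_micro[[chunk_i]] <- w[im]
      if (keep_microorganism_phase_space && length(im)) {
        phsp_m[[chunk_i]] <- .phase_space_records(
          tr, im, em, "microorganism", sp$nuclide, done,
          tr$t_microorganism, tr$energy_at_microorganism)
      }
      if (length(iN)) {
        phsp_n[[chunk_i]] <- .phase_space_records(
          tr, iN, em, "nucleus", sp$nuclide, done,
          tr$t_nucleus, tr$energy_at_nucleus)
      }
      done <- done + m
    }
    e_micro <- unlist(e_micro); w_micro <- unlist(w_micro)
    doses <- c(
      microorganism = dep_tot[["microorganism"]] * .MEV_TO_J / masses$microorganism,
      nucleus = dep_tot[["nucleus"]] * .MEV_TO_J / masses$nucleus,
      frustule = if (g$frustule_thickness > 0)
        dep_tot[["frustule"]] * .MEV_TO_J / masses$frustule else 0
    )
    rel_sd <- if (sum(batch_micro) > 0) {
      stats::sd(batch_micro) / mean(batch_micro) / sqrt(n_batches)
    } else NA_real_
    per_nuclide[[nuc]] <- list(
      nuclide = sp$nuclide,
      n_primaries = n_primaries,
      deposits_mev = dep_tot,
      dose_gy = doses,
      dose_rel_sd = rel_sd,
      entered_microorganism = n_entered_m,
      entered_nucleus = n_entered_n,
      fraction_entering_microorganism = w_entered_m / n_primaries,
      fraction_entering_nucleus = w_entered_n / n_primaries,
      mean_entry_energy = if (length(e_micro))
        sum(w_micro * e_micro) / sum(w_micro) else NA_real_,
      max_entry_energy = if (length(e_micro)) max(e_micro) else NA_real_,
      phase_space_microorganism = .bind_phsp(phsp_m),
      phase_space_nucleus = .bind_phsp(phsp_n)
    )
  }
  structure(list(scenario = scenario, per_nuclide = per_nuclide,
                 n_primaries = n_primaries, toward_nucleus = toward_nucleus,
                 seed = seed),
            class = "microdose_result")
}

.phase_space_records <- function(tr, idx, em, surface, nuclide, offset,
                                 t_entry, e_entry) {
  p <- em$position[idx, , drop = FALSE] +
    em$direction[idx, , drop = FALSE] * t_entry[idx]
  data.frame(
    particle = "alpha",
    E_MeV = e_entry[idx],
    x_um = p[, 1], y_um = p[, 2], z_um = p[, 3],
    dx = em$direction[idx, 1], dy = em$direction[idx, 2],
    dz = em$direction[idx, 3],
    surface = surface, nuclide = nuclide,
    primary_id = offset + idx,
    weight = em$weight[idx]
  )
}

.bind_phsp <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) {
    return(data.frame(particle = character(0), E_MeV = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      dx = numeric(0), dy = numeric(0), dz = numeric(0),
                      surface = character(0), nuclide = character(0),
                      primary_id = integer(0), weight = numeric(0)))
  }
  do.call(rbind, lst)
}

#' @export
print.microdose_result <- function(x, ...) {
  cat(sprintf("microdose result: %g primaries per nuclide%s\n",
              x$n_primaries,
              if (x$toward_nucleus) " (nucleus-aimed, weighted)" else ""))
  for (r in x$per_nuclide) {
    cat(sprintf("  %s: microorganism dose %.3e Gy/primary (rel SD %.2g), entry fraction %.3g%%, nucleus fraction %.3g%%\n",
                r$nuclide, r$dose_gy[["microorganism"]] / r$n_primaries,
                r$dose_rel_sd,
                100 * r$fraction_entering_microorganism,
                100 * r$fraction_entering_nucleus))
  }
  invisible(x)
}

#' Write or read a phase-space file
#'
#' Columnar CSV with header, columns in this order: `particle`, `E_MeV`,
#' `x_um`, `y_um`, `z_um`, `dx`, `dy`, `dz`, `surface`, `nuclide`,
#' `primary_id`, `weight`.
#'
#' @param phase_space phase-space data.frame from [run_microdose()]
#' @param path file path
#' @return `read_phase_space` returns the phase-space data.frame
#' @export
write_phase_space <- function(phase_space, path) {
  cols <- c("particle", "E_MeV", "x_um", "y_um", "z_um", "dx", "dy", "dz",
            "surface", "nuclide", "primary_id", "weight")
  stopifnot(all(cols %in% names(phase_space)))
  utils::write.csv(phase_space[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_space
#' @export
read_phase_space <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Quadrature oracle for the geometric entry fraction
#'
#' For a monoenergetic, isotropic, volume-uniform source in a single-material
#' environment (no frustule), the probability that an emitted alpha reaches a
#' target sphere of radius `r_target` is a one-dimensional integral over the
#' emission radius `d` of the effective cone fraction
#' \eqn{(1 - \mu^*(d))/2}, where \eqn{\mu^*} is the larger of the geometric
#' cone limit \eqn{\sqrt{1 - (r_t/d)^2}} and the range limit
#' \eqn{(d^2 + s^2 - r_t^2)/(2ds)} with `s` the maximum geometric path
#' (water range divided by the environment's linear stopping scaling).
#'
#' @param geometry a [cell_geometry()] with `frustule_thickness == 0`
#' @param energy alpha energy in MeV (single value)
#' @param target `"microorganism"` or `"nucleus"`
#' @param model a [range_energy_model()]
#' @return expected entry fraction (probability)
#' @export
entry_fraction_quadrature <- function(geometry, energy,
                                      target = c("microorganism", "nucleus"),
                                      model = default_range_model()) {
  target <- match.arg(target)
  if (geometry$frustule_thickness > 0) {
    stop("quadrature oracle only supports geometries without a frustule")
  }
  r_t <- switch(target, microorganism = geometry$r_microorganism,
                nucleus = geometry$r_nucleus)
  f_env <- .linear_scaling(geometry$environment_material)
  s_max <- csda_range(energy, model) / f_env
  extra <- if (target == "nucleus") {
    # water path inside the microorganism before the nucleus surface is at
    # unit scaling: account for it by shrinking the environment budget
    (geometry$r_microorganism - geometry$r_nucleus) * (1 - 1 / f_env)
  } else 0
  omega <- function(d) {
    mu_geo <- sqrt(pmax(1 - (r_t / d)^2, 0))
    # for the nucleus target the ray crosses (r_m - r_n) of water; fold that
    # into an effective geometric budget s_eff measured in environment um
    s_eff <- s_max + extra
    # the range constraint binds only for rays whose entry path exceeds
    # s_eff; the longest entry path of a hitting ray is the tangent length
    tangent <- sqrt(pmax(d^2 - r_t^2, 0))
    mu_rng <- (d^2 + s_eff^2 - r_t^2) / (2 * d * s_eff)
    mu_star <- ifelse(tangent <= s_eff, mu_geo, mu_rng)
    mu_star <- pmin(pmax(mu_star, mu_geo), 1)
    (1 - mu_star) / 2
  }
  r_in <- geometry$r_outer
  num <- stats::integrate(function(d) d^2 * omega(d), r_in, geometry$r_env,
                          rel.tol = 1e-9)$value
  den <- (geometry$r_env^3 - r_in^3) / 3
  num / den
}
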