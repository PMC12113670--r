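## diagnostics: field extrema, convection-cell counting, Ran sweeps with
## onset estimation, mesh-independence harness.

#' Global field extrema of a state
#'
#' @param state a `field_state`.
#' @return A list with `psi_max` (largest \eqn{|\psi|}), `psi_extremum`
#'   (the same extremal value with its sign), and the maxima `phi_max`,
#'   `n_max`, `theta_max`.
#' @export
global_extrema <- function(state) {
  psi <- state$psi
  if (!all(is.finite(psi)))
    stop("global_extrema: state contains non-finite values", call. = FALSE)
  k <- which.max(abs(psi))
  list(psi_max = abs(psi[k]), psi_extremum = psi[k],
       phi_max = max(state$phi), n_max = max(state$n),
       theta_max = max(state$theta))
}

#' Count convection cells (rolls) in a stream-function field
#'
#' Thresholded sign-domain labelling: grid nodes with
#' \eqn{|\psi| > } `threshold_frac` \eqn{\times \max|\psi|} are grouped into
#' 4-connected regions separately for each sign of \eqn{\psi}; each region
#' is one roll.  Regions whose extrema are not separated by a sign change or
#' by a dip below the threshold merge, matching how rolls are counted from
#' streamline plots.  Returns 0 when \eqn{\max|\psi| < 10^{-10}}.
#'
#' @param psi stream-function matrix.
#' @param g a [make_grid()] grid.
#' @param threshold_frac relative magnitude cutoff in (0, 1); default 0.05.
#' @return Integer number of cells.
#' @export
count_convection_cells <- function(psi, g, threshold_frac = 0.05) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  pmax <- max(abs(psi))
  if (pmax < 1e-10) return(0L)
  thr <- threshold_frac * pmax
  lab <- matrix(0L, nrow(psi), ncol(psi))
  mask_pos <- psi > thr
  mask_neg <- psi < -thr
  count <- 0L
  for (mask in list(mask_pos, mask_neg)) {
    todo <- which(mask & lab == 0L)
    while (length(todo)) {
      count <- count + 1L
      queue <- todo[1]
      lab[queue] <- count
      nr <- nrow(psi)
      while (length(queue)) {
        k <- queue[[1]]; queue <- queue[-1]
        i <- (k - 1L) %% nr + 1L
        j <- (k - 1L) %/% nr + 1L
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1L && ii <= nr && jj >= 1L && jj <= ncol(psi)) {
            kk <- (jj - 1L) * nr + ii
            if (mask[kk] && lab[kk] == 0L) {
              lab[kk] <- count
              queue <- c(queue, kk)
            }
          }
        }
      }
      todo <- which(mask & lab == 0L)
    }
  }
  count
}

#' Sweep the nanoparticle Rayleigh number
#'
#' Runs [run_to_convergence()] for each value of `Ran`, warm-starting every
#' run from the previous converged state, and collects \eqn{|\psi|_{max}},
#' \eqn{\phi_{max}} and the cell count.
#'
#' @param base a [case_config()]; all parameters except `Ran` stay fixed.
#' @param ran_values strictly increasing numeric vector of `Ran` values.
#' @param keep_states logical; also return the converged states (used e.g.
#'   to inspect roll patterns at selected `Ran`).
#' @return An object of class `sweep_result`: a list with the per-value
#'   vectors `ran_values`, `psi_max`, `phi_max`, `cell_counts`, `converged`,
#'   a `ran_critical` estimate (see [estimate_critical_ran()]; `NA` when no
#'   onset is detected or fewer than 3 runs converged), and optionally
#'   `states`.  `as.data.frame()` yields the tabular form.
#' @export
sweep_ran <- function(base, ran_values, keep_states = FALSE) {
  stopifnot(inherits(base, "case_config"), length(ran_values) >= 1)
  if (is.unsorted(ran_values, strictly = TRUE))
    stop("sweep_ran: ran_values must be strictly increasing", call. = FALSE)
  m <- length(ran_values)
  psi_max <- phi_max <- numeric(m)
  cells <- integer(m)
  conv <- logical(m)
  states <- if (keep_states) vector("list", m)
  prev <- NULL
  for (k in seq_len(m)) {
    cfg <- base
    cfg$params$Ran <- ran_values[k]
    rr <- run_to_convergence(cfg, initial = prev)
    psi_max[k] <- rr$diagnostics$psi_max
    phi_max[k] <- rr$diagnostics$phi_max
    cells[k] <- rr$diagnostics$cells
    conv[k] <- rr$converged
    if (keep_states) states[[k]] <- rr$state
    prev <- rr$state
  }
  sw <- structure(list(ran_values = ran_values, psi_max = psi_max,
                       phi_max = phi_max, cell_counts = cells,
                       converged = conv, ran_critical = NA_real_),
                  class = "sweep_result")
  if (sum(conv) >= 3)
    sw$ran_critical <- estimate_critical_ran(sw)
  if (keep_states) sw$states <- states
  sw
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(ran = x$ran_values, psi_max = x$psi_max, phi_max = x$phi_max,
             cells = x$cell_counts, converged = x$converged)
}

#' Estimate the critical nanoparticle Rayleigh number from a sweep
#'
#' Onset detector on the \eqn{|\psi|_{max}}-vs-`Ran` curve: returns the
#' midpoint of the first sweep interval whose discrete slope exceeds
#' `slope_factor` times the median slope of the preceding intervals (a
#' slope-jump rule).  Flat curves yield `NA` (no onset).  The estimate is
#' invariant under uniform positive rescaling of the `psi_max` values.
#'
#' @param sweep a `sweep_result` (non-converged points are excluded).
#' @param slope_factor slope-jump threshold factor, default 5.
#' @return The estimated onset `Ran`, or `NA_real_` when no slope jump is
#'   found.
#' @export
estimate_critical_ran <- function(sweep, slope_factor = 5) {
  stopifnot(inherits(sweep, "sweep_result"))
  keep <- sweep$converged
  ran <- sweep$ran_values[keep]
  psi <- sweep$psi_max[keep]
  if (length(ran) < 3)
    stop("estimate_critical_ran: need at least 3 converged sweep points",
         call. = FALSE)
  slope <- diff(psi) / diff(ran)
  for (k in 2:length(slope)) {
    med <- median(slope[1:(k - 1)])
    if (slope[k] > 0 && slope[k] > slope_factor * max(med, 0))
      return((ran[k] + ran[k + 1]) / 2)
  }
  NA_real_
}

#' Mesh-independence study
#'
#' Runs the base configuration to convergence on each mesh at each probe
#' `Ran`, reports \eqn{|\psi|_{max}} and \eqn{\phi_{max}} per mesh, and
#' selects the coarsest mesh whose diagnostics differ from the finest
#' mesh's by less than 0.5% (relative) at every probe.
#'
#' @param base a [case_config()] (its grid is replaced by each mesh).
#' @param meshes list of [make_grid()] grids, ordered coarse to fine.
#' @param probe_ran numeric vector of `Ran` values to probe.
#' @return An object of class `mesh_study_report`: data frame `table` with
#'   one row per mesh and columns `mesh`, then `phi_max_<ran>` /
#'   `psi_max_<ran>` per probe, plus `rel_diff` (max relative difference to
#'   the finest mesh) and `converged`; and `selected` (index of the selected
#'   mesh).
#' @export
mesh_independence_study <- function(base, meshes, probe_ran) {
  stopifnot(inherits(base, "case_config"), length(meshes) >= 2,
            length(probe_ran) >= 1)
  nm <- length(meshes)
  phi <- psi <- matrix(NA_real_, nm, length(probe_ran))
  conv <- matrix(NA, nm, length(probe_ran))
  for (m in seq_len(nm)) {
    g <- meshes[[m]]
    stopifnot(inherits(g, "bc_grid"))
    cfg <- base
    cfg$grid <- g
    prev <- NULL
    for (k in seq_along(probe_ran)) {
      cfg$params$Ran <- probe_ran[k]
      rr <- run_to_convergence(cfg, initial = prev)
      phi[m, k] <- rr$diagnostics$phi_max
      psi[m, k] <- rr$diagnostics$psi_max
      conv[m, k] <- rr$converged
      prev <- rr$state
    }
  }
  rel <- vapply(seq_len(nm), function(m) {
    max(abs(phi[m, ] - phi[nm, ]) / abs(phi[nm, ]),
        abs(psi[m, ] - psi[nm, ]) / abs(psi[nm, ]))
  }, numeric(1))
  selected <- which(rel < 0.005)[1]
  tab <- data.frame(
    mesh = vapply(meshes, function(g) paste0(g$Nx1, "x", g$Nx2), ""),
    stringsAsFactors = FALSE)
  for (k in seq_along(probe_ran)) {
    tab[[paste0("phi_max_", probe_ran[k])]] <- phi[, k]
    tab[[paste0("psi_max_", probe_ran[k])]] <- psi[, k]
  }
  tab$rel_diff <- rel
  tab$converged <- apply(conv, 1, all)
  structure(list(table = tab, selected = selected, probe_ran = probe_ran),
            class = "mesh_study_report")
}

#' @export
print.mesh_study_report <- function(x, ...) {
  cat("<mesh_study_report> selected mesh:",
      if (is.na(x$selected)) "none" else x$table$mesh[x$selected], "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
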