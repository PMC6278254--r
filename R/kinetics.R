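# ---------------------------------------------------------------------------
# Deterministic mass-action integration of a CRN.
# Concentrations are nM internally; readouts are reported in units of the
# 10,000 nM unit concentration.
# ---------------------------------------------------------------------------

crn_indices <- function(x) {
  sp <- x$species$species
  idx <- seq_along(sp)
  names(idx) <- sp
  nr <- nrow(x$reactions)
  i1 <- integer(nr); i2 <- integer(nr)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (j in seq_len(nr)) {
    r <- x$reactions$reactants[[j]]
    p <- x$reactions$products[[j]]
    i1[[j]] <- idx[[r[[1L]]]]
    i2[[j]] <- if (length(r) > 1L) idx[[r[[2L]]]] else 0L
    trip_i <- c(trip_i, idx[r], idx[p])
    trip_j <- c(trip_j, rep(j, length(r) + length(p)))
    trip_x <- c(trip_x, rep(-1, length(r)), rep(1, length(p)))
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(sp), nr))
  list(names = sp, i1 = i1, i2 = i2, k = x$reactions$rate, S = S,
       bi = which(i2 > 0L))
}

crn_rhs <- function(ind) {
  force(ind)
  function(t, y, parms) {
    y[y < 0] <- 0
    v <- ind$k * y[ind$i1]
    v[ind$bi] <- v[ind$bi] * y[ind$i2[ind$bi]]
    list(as.vector(ind$S %*% v))
  }
}

#' Integrate a CRN under mass-action kinetics
#'
#' Stiff-capable deterministic integration of `d[x]/dt` from the mass-action
#' stoichiometry.  All reported concentrations are non-negative and
#' conserved strand totals stay constant to within solver tolerance.
#'
#' @param x A `dsd_crn`.
#' @param t_end End time, s.  The reference circuits settle well before the
#'   default 10,000 s.
#' @param times Optional vector of report times (s); defaults to a
#'   log-spaced grid over `(0, t_end]`.
#' @param rtol,atol Relative / absolute (nM) solver tolerances.
#' @param method `deSolve` integrator; `"lsodes"` exploits the sparse
#'   stoichiometry.
#' @return A `dsd_trajectory`.
#' @examples
#' toy <- crn(tibble::tibble(species = c("A", "B", "C"), conc_nM = c(1e4, 1e4, 0)),
#'            tibble::tibble(reactants = list(c("A", "B")), products = list("C"),
#'                           rate = 3e-5))
#' traj <- simulate_crn(toy, t_end = 100)
#' @export
simulate_crn <- function(x, t_end = 1e4, times = NULL, rtol = 1e-8,
                         atol = 1e-6, method = "lsodes") {
  stopifnot(inherits(x, "dsd_crn"), t_end > 0)
  if (any(x$species$conc_nM < 0)) abort("negative initial concentration")
  ind <- crn_indices(x)
  if (is.null(times)) {
    times <- unique(c(0, exp(seq(log(max(t_end * 1e-5, 1e-3)), log(t_end),
                                 length.out = 120L))))
  }
  rhs <- crn_rhs(ind)
  out <- tryCatch(
    deSolve::ode(y = x$species$conc_nM, times = times, func = rhs,
                 parms = NULL, method = method, rtol = rtol, atol = atol),
    warning = function(w) {
      abort(sprintf("ODE solver reported a problem near t = %s: %s",
                    format(times[length(times)]), conditionMessage(w)))
    })
  conc <- unname(out[, -1L, drop = FALSE])
  colnames(conc) <- ind$names
  final_deriv <- rhs(t_end, conc[nrow(conc), ], NULL)[[1L]]
  names(final_deriv) <- ind$names
  structure(list(times = out[, 1L], conc = conc, species = ind$names,
                 crn = x, unit_nM = x$unit_nM, final_deriv = final_deriv),
            class = "dsd_trajectory")
}

#' @export
print.dsd_trajectory <- function(x, ...) {
  cat(sprintf("<dsd_trajectory> %d species over [0, %g] s (%d points)\n",
              length(x$species), max(x$times), length(x$times)))
  invisible(x)
}

#' Fluorophore species of a CRN or trajectory
#'
#' @param x A `dsd_crn` or `dsd_trajectory`.
#' @return Character vector of fluorophore strand species.
#' @export
fluorophore_species <- function(x) {
  sp <- if (inherits(x, "dsd_trajectory")) x$species else x$species$species
  sp[grepl("^<[^]{}<>]* fluor>$", sp)]
}

#' Interpolated readout of species concentrations
#'
#' @param traj A `dsd_trajectory`.
#' @param species Species names (canonical text).
#' @param t Time, s, within the trajectory span; defaults to the end.
#' @param units Report in units of the 10,000 nM unit concentration
#'   (default) or in nM.
#' @return Tibble with `species`, `time` and `value`.
#' @export
readout <- function(traj, species = fluorophore_species(traj),
                    t = max(traj$times), units = TRUE) {
  stopifnot(inherits(traj, "dsd_trajectory"))
  missing <- setdiff(species, traj$species)
  if (length(missing) > 0L)
    abort(paste0("unknown species: ", missing[[1L]]))
  if (t < min(traj$times) || t > max(traj$times))
    abort("readout time outside the trajectory span")
  vals <- map_dbl(species, function(s) {
    stats::approx(traj$times, traj$conc[, s], xout = t, rule = 2L)$y
  })
  scale <- if (units) traj$unit_nM else 1
  tibble(species = species, time = t, value = vals / scale)
}

#' Has a trajectory settled?
#'
#' Settled means the fluorophore derivatives at the final time are all below
#' `tol` units/s.
#'
#' @param traj A `dsd_trajectory`.
#' @param species Species to test; defaults to all fluorophores.
#' @param tol Units per second.
#' @return Logical.
#' @export
is_settled <- function(traj, species = fluorophore_species(traj), tol = 1e-6) {
  if (length(species) == 0L) return(TRUE)
  all(abs(traj$final_deriv[species]) / traj$unit_nM < tol)
}

#' First time a set of species reaches a level
#'
#' Linear-interpolated first crossing of `level` (units) by every species in
#' the set; used to compare cascade settle times with the order of magnitude
#' of reference traces.
#'
#' @param traj A `dsd_trajectory`.
#' @param species Species names.
#' @param level Level in units.
#' @return Time in s, or `NA` if some species never reaches the level.
#' @export
settle_time <- function(traj, species, level = 0.9) {
  crossing <- map_dbl(species, function(s) {
    y <- traj$conc[, s] / traj$unit_nM
    i <- which(y >= level)
    if (length(i) == 0L) return(NA_real_)
    i0 <- i[[1L]]
    if (i0 == 1L) return(traj$times[[1L]])
    t0 <- traj$times[[i0 - 1L]]; t1 <- traj$times[[i0]]
    y0 <- y[[i0 - 1L]]; y1 <- y[[i0]]
    t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  })
  if (anyNA(crossing)) NA_real_ else max(crossing)
}

#' Conserved linear combinations of a CRN
#'
#' Left null vectors of the stoichiometry matrix; along any mass-action
#' trajectory the corresponding linear combinations of concentrations are
#' exact invariants (per-strand conservation laws).
#'
#' @param x A `dsd_crn`.
#' @param tol Singular-value tolerance.
#' @return Matrix (species x invariants), possibly with zero columns.
#' @export
conserved_moieties <- function(x, tol = 1e-9) {
  ind <- crn_indices(x)
  S <- as.matrix(ind$S)
  sv <- svd(S, nu = nrow(S), nv = 0L)
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r >= nrow(S)) {
    return(matrix(numeric(0), nrow = nrow(S), ncol = 0L,
                  dimnames = list(ind$names, NULL)))
  }
  out <- sv$u[, (r + 1L):nrow(S), drop = FALSE]
  rownames(out) <- ind$names
  out
}

#' Maximum drift of conserved totals along a trajectory
#'
#' @param traj A `dsd_trajectory`.
#' @return Largest absolute drift of any conservation law, in units.
#' @export
conservation_drift <- function(traj) {
  L <- conserved_moieties(traj$crn)
  if (ncol(L) == 0L) return(0)
  tot <- traj$conc %*% L
  max(apply(tot, 2L, function(z) diff(range(z)))) / traj$unit_nM
}

#' @exportS3Method generics::tidy
tidy.dsd_trajectory <- function(x, ...) {
  tibble(
    time = rep(x$times, times = length(x$species)),
    species = rep(x$species, each = length(x$times)),
    conc_nM = as.vector(x$conc),
    units = as.vector(x$conc) / x$unit_nM
  )
}

#' @exportS3Method generics::glance
glance.dsd_trajectory <- function(x, ...) {
  tibble(n_species = length(x$species), t_end = max(x$times),
         settled = is_settled(x))
}

#' Plot species trajectories
#'
#' @param object A `dsd_trajectory`.
#' @param species Species to draw; defaults to the fluorophores.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dsd_trajectory <- function(object, species = fluorophore_species(object),
                                    ...) {
  dat <- tidy.dsd_trajectory(object)
  dat <- dat[dat$species %in% species, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$units,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (units)") +
    ggplot2::theme_minimal()
}

#' Write a trajectory as CSV
#'
#' One `time` column (s) plus one column per species (nM), canonical species
#' names in the header.
#'
#' @param traj A `dsd_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "dsd_trajectory"))
  df <- data.frame(time = traj$times, traj$conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
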