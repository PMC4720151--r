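#' Parameters of the continuous (fuzzy-logic sigmoid ODE) system
#'
#' Each ruled node i evolves as
#' `dx_i/dt = f(omega_i; h_i) - gamma_i * x_i`, where `omega_i` is the
#' fuzzified logic rule of the node evaluated on the current activation
#' levels, and `f` is a normalised sigmoid gain function (see
#' [sigmoid_activation()]).  Regulator-free input nodes carry only the decay
#' term `-gamma_i * x_i`.  All variables are dimensionless activation levels
#' in `[0, 1]`; time is in arbitrary units.
#'
#' @param net a [regulatory_network].
#' @param h sigmoid gain, scalar or named per-node vector (default 50:
#'   a near step-like response).
#' @param gamma decay rate per unit time, scalar or named per-node vector
#'   (default 1, the value for which steady levels span the full `[0, 1]`
#'   range, since the saturated steady state is `f(omega)/gamma`).
#' @param convergence_tol relaxation stops when `max |dx/dt|` falls below
#'   this residual (default 1e-10).
#' @param max_time give up flagging non-convergence after this much
#'   integration time (default 500).
#' @param merge_tol converged states closer than this (after rounding) are
#'   considered the same attractor (default 1e-6).
#' @return an object of class `squad_params`.
#' @export
squad_params <- function(net, h = 50, gamma = 1, convergence_tol = 1e-10,
                         max_time = 500, merge_tol = 1e-6) {
  assert_network(net)
  expand <- function(v, what) {
    if (length(v) == 1L && is.null(names(v)))
      v <- stats::setNames(rep(as.numeric(v), length(net$nodes)), net$nodes)
    else {
      unknown <- setdiff(names(v), net$nodes)
      if (length(unknown) > 0L)
        stop(what, " given for unknown node(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      full <- stats::setNames(rep(NA_real_, length(net$nodes)), net$nodes)
      full[names(v)] <- as.numeric(v)
      if (anyNA(full))
        stop(what, " must cover all nodes or be a scalar", call. = FALSE)
      v <- full
    }
    if (any(v <= 0)) stop(what, " must be > 0", call. = FALSE)
    v[net$nodes]
  }
  structure(list(h = expand(h, "h"), gamma = expand(gamma, "gamma"),
                 convergence_tol = convergence_tol, max_time = max_time,
                 merge_tol = merge_tol),
            class = "squad_params")
}

#' Normalised sigmoid activation function
#'
#' The gain function
#' `f(omega) = (-exp(h/2) + exp(-h(omega - 1/2))) /
#'             ((1 - exp(h/2)) (1 + exp(-h(omega - 1/2))))`
#' passes through (0,0), (0.5,0.5) and (1,1) for every positive gain `h`.
#' Small `h` gives a nearly linear response, intermediate `h` a logistic
#' curve, and `h >= 50` a near step function.  The implementation factors
#' the exponentials so that no intermediate overflows for arbitrarily large
#' `h` (the naive form overflows near `h ~ 1400`).
#'
#' @param omega fuzzified regulatory input, in `[0, 1]` (vectorised).
#' @param h gain, `> 0`.
#' @return activation in `[0, 1]`, same length as `omega`.
#' @examples
#' sigmoid_activation(c(0, 0.5, 1), h = 50)  # exactly 0, 0.5, 1
#' @export
sigmoid_activation <- function(omega, h) {
  if (any(h <= 0)) stop("h must be > 0", call. = FALSE)
  h <- rep_len(h, length(omega))
  u <- h * (omega - 0.5)
  a <- 0.5 * h
  d <- 1 - exp(-a)
  out <- numeric(length(u))
  pos <- u >= 0
  # algebraically identical branches, each overflow-free on its half-range
  out[pos] <- (1 - exp(-u[pos] - a[pos])) / (d[pos] * (1 + exp(-u[pos])))
  out[!pos] <- (exp(u[!pos]) - exp(-a[!pos])) / (d[!pos] * (1 + exp(u[!pos])))
  # the anchors are exact by construction; enforce them against the last
  # ulp of rounding in the factored denominators
  out[omega == 0] <- 0
  out[omega == 1] <- 1
  out
}

#' Fuzzified rule set of a network
#'
#' @param net a [regulatory_network].
#' @return named list of fuzzy expressions (see [fuzzify_rule()]), one per
#'   ruled node.
#' @export
fuzzy_rules <- function(net) {
  assert_network(net)
  lapply(net$rules, fuzzify_rule)
}

#' Right-hand side of the continuous system
#'
#' For ruled nodes the rate is `sigmoid(omega) - gamma * x`; input nodes
#' decay (`-gamma * x`); clamped nodes have rate 0 (their level is pinned).
#'
#' @param net a [regulatory_network].
#' @param params a [squad_params] object.
#' @param state named numeric vector of levels in `[0, 1]`.
#' @param clamps optional named vector of levels pinned during integration.
#' @return named numeric rate vector.
#' @export
continuous_derivative <- function(net, params, state, clamps = NULL) {
  rhs <- make_rhs(net, params, as_clamp_set(net, clamps, continuous = TRUE))
  x <- as_continuous_state(net, state)
  stats::setNames(rhs(0, x, NULL)[[1]], net$nodes)
}

as_continuous_state <- function(net, state) {
  if (is.null(names(state)))
    stop("state must be a named vector", call. = FALSE)
  missing <- setdiff(net$nodes, names(state))
  if (length(missing) > 0L)
    stop("state does not assign node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(state[net$nodes])
  if (any(v < -1e-8 | v > 1 + 1e-8))
    stop("activation levels must lie in [0, 1]", call. = FALSE)
  names(v) <- net$nodes
  pmin(pmax(v, 0), 1)
}

# build a deSolve-compatible rhs closure; clamped nodes contribute rate 0.
# the fuzzified rules are compiled into one positional-index expression so a
# single eval yields all omega values per call
make_rhs <- function(net, params, cl) {
  nodes <- net$nodes
  fz <- fuzzy_rules(net)
  ruled_idx <- match(names(fz), nodes)
  index_expr <- function(e) {
    if (is.symbol(e))
      return(call("[[", quote(x), match(as.character(e), nodes)))
    if (is.call(e)) {
      for (i in seq_along(e)[-1]) e[[i]] <- index_expr(e[[i]])
      return(e)
    }
    e
  }
  omega_fun <- function(x) NULL
  body(omega_fun) <- as.call(c(as.name("c"),
                               lapply(unname(fz), index_expr)))
  environment(omega_fun) <- baseenv()
  omega_fun <- compiler::cmpfun(omega_fun)
  h <- unname(params$h[ruled_idx])
  gamma <- unname(params$gamma)
  clamped_idx <- match(names(cl), nodes)
  function(t, x, parms) {
    dx <- -gamma * x
    if (length(ruled_idx) > 0L)
      dx[ruled_idx] <- sigmoid_activation(omega_fun(x), h) +
        dx[ruled_idx]
    if (length(clamped_idx) > 0L) dx[clamped_idx] <- 0
    list(dx)
  }
}

#' Relax the continuous system to a steady state
#'
#' Integrates the stiff ODE system (adaptive `lsoda`) in chunks until the
#' residual `max |dx/dt|` drops below `params$convergence_tol`, or flags the
#' result as non-converged at `params$max_time`.
#'
#' @inheritParams continuous_derivative
#' @param x0 named initial levels in `[0, 1]`.
#' @param chunk integration time per convergence check (default 25).
#' @return an object of class `continuous_attractor`: list with `levels`
#'   (named numeric), `residual`, `time`, `converged` (logical) and
#'   `discovered_by`.
#' @examples
#' \donttest{
#' net <- load_bcell_network()
#' p <- squad_params(net)
#' relax(net, p, make_state(net, c("Bach2", "Bcl6", "Pax5")))$levels["Bcl6"]
#' }
#' @export
relax <- function(net, params, x0, clamps = NULL, chunk = 25) {
  assert_network(net)
  stopifnot(inherits(params, "squad_params"))
  cl <- as_clamp_set(net, clamps, continuous = TRUE)
  x <- as_continuous_state(net, x0)
  if (length(cl) > 0L) x[names(cl)] <- cl
  rhs <- make_rhs(net, params, cl)
  t <- 0
  resid <- max(abs(rhs(t, x, NULL)[[1]]))
  while (resid >= params$convergence_tol && t < params$max_time) {
    t1 <- min(t + chunk, params$max_time)
    sol <- deSolve::lsoda(y = x, times = c(t, t1), func = rhs,
                          rtol = 1e-10, atol = 1e-12)
    x <- sol[nrow(sol), net$nodes]
    if (length(cl) > 0L) x[names(cl)] <- cl   # pin against integration drift
    t <- t1
    resid <- max(abs(rhs(t, x, NULL)[[1]]))
  }
  structure(list(levels = stats::setNames(as.numeric(x), net$nodes),
                 residual = resid, time = t,
                 converged = resid < params$convergence_tol,
                 discovered_by = "relaxation"),
            class = "continuous_attractor")
}

#' @export
print.continuous_attractor <- function(x, ...) {
  on <- names(x$levels)[x$levels > 1e-3]
  cat(sprintf("Continuous %s (residual %.2e, t = %g)\n",
              if (x$converged) "steady state" else "NON-CONVERGED state",
              x$residual, x$time))
  cat("  active:", if (length(on) > 0)
    paste(sprintf("%s=%.3g", on, x$levels[on]), collapse = ", ")
    else "(none)", "\n")
  invisible(x)
}

# snap converged levels onto the merge grid: removes integrator residue
# (~1e-11) so that downstream perturbation protocols start from the
# idealised attractor state and are reproducible across seeds
snap_levels <- function(levels, merge_tol) {
  digits <- max(0L, ceiling(-log10(merge_tol)))
  r <- round(levels, digits)
  r[r == 0] <- 0
  r
}

# merge key for clustering converged states
level_key <- function(levels, merge_tol) {
  digits <- max(0L, ceiling(-log10(merge_tol)))
  r <- round(levels, digits)
  r[r == 0] <- 0   # fold negative zero
  paste(sprintf(paste0("%.", digits, "f"), r), collapse = "|")
}

#' Random-start sampling of continuous attractors
#'
#' Draws `n_runs` initial states uniformly in `[0,1]^n`, relaxes each and
#' clusters the converged states within `params$merge_tol`.
#'
#' @inheritParams relax
#' @param n_runs number of random initial states (default 5000; attractor
#'   identity rather than basin estimation is the goal at this scale).
#' @param seed optional RNG seed for reproducible draws.
#' @return an object of class `continuous_attractor_set`: list of distinct
#'   attractors, each carrying `levels`, `support_count` (runs converging
#'   there), `residual` and `discovered_by = "random_start"`.  Attribute
#'   `n_nonconverged` counts flagged runs.
#' @export
sample_attractors <- function(net, params, n_runs = 5000, seed = NULL,
                              clamps = NULL) {
  assert_network(net)
  stopifnot(n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  starts <- matrix(stats::runif(n_runs * length(net$nodes)),
                   nrow = n_runs, dimnames = list(NULL, net$nodes))
  found <- list()
  n_bad <- 0L
  for (r in seq_len(n_runs)) {
    res <- relax(net, params, starts[r, ], clamps = clamps)
    if (!res$converged) { n_bad <- n_bad + 1L; next }
    key <- level_key(res$levels, params$merge_tol)
    if (is.null(found[[key]])) {
      res$support_count <- 1L
      res$discovered_by <- "random_start"
      res$levels_min <- res$levels
      res$levels_max <- res$levels
      found[[key]] <- res
    } else {
      found[[key]]$support_count <- found[[key]]$support_count + 1L
      found[[key]]$levels_min <- pmin(found[[key]]$levels_min, res$levels)
      found[[key]]$levels_max <- pmax(found[[key]]$levels_max, res$levels)
    }
  }
  # numerical spread of converged levels across the cluster's runs
  for (key in names(found))
    found[[key]]$spread <- max(found[[key]]$levels_max -
                               found[[key]]$levels_min)
  out <- found[order(-vapply(found, `[[`, 0L, "support_count"))]
  structure(unname(out), class = "continuous_attractor_set",
            nodes = net$nodes, n_runs = n_runs, n_nonconverged = n_bad)
}

#' @export
print.continuous_attractor_set <- function(x, ...) {
  cat("Continuous attractor set:", length(x), "distinct steady state(s)\n")
  for (i in seq_along(x)) {
    a <- x[[i]]
    on <- names(a$levels)[a$levels > 1e-3]
    cat(sprintf("  %d. {%s}  support %s  via %s\n", i,
                paste(sprintf("%s=%.3g", on, a$levels[on]), collapse = ","),
                if (is.null(a$support_count)) "-" else a$support_count,
                a$discovered_by))
  }
  invisible(x)
}

#' Perturbation-based discovery of additional attractors
#'
#' For every base attractor, node and perturbation level, the node is
#' transiently clamped at that level for `duration` time units, released,
#' and the system relaxed.  Newly discovered steady states (with
#' intermediate activation levels, invisible to random sampling) are added
#' flagged `discovered_by = "perturbation"`; every (source, perturbation,
#' destination) triple is recorded.
#'
#' @inheritParams relax
#' @param base_attractors a `continuous_attractor_set` (or list of
#'   `continuous_attractor`s) to perturb.
#' @param levels transient clamp levels (default `c(0, 0.5, 1)`, the
#'   off / intermediate / saturating perturbations).
#' @param duration clamp duration in time units (default 10).
#' @return list with `attractors` (a `continuous_attractor_set`, union of
#'   base and new) and `transitions` (data.frame: source, node, level,
#'   destination, new_attractor).
#' @export
perturbation_search <- function(net, params, base_attractors,
                                levels = c(0, 0.5, 1), duration = 10) {
  assert_network(net)
  base <- lapply(base_attractors, identity)
  pool <- list()
  for (a in base) pool[[level_key(a$levels, params$merge_tol)]] <- a
  trans <- list()
  for (i in seq_along(base)) {
    # perturb the idealised attractor state, not the integrator's endpoint:
    # the discovery protocol is then independent of ~1e-11 residuals
    src_levels <- snap_levels(base[[i]]$levels, params$merge_tol)
    for (nm in net$nodes) {
      for (lv in levels) {
        dest <- pulse_and_relax(net, params, src_levels, nm, lv, duration)
        if (!dest$converged) next
        key <- level_key(dest$levels, params$merge_tol)
        is_new <- is.null(pool[[key]])
        if (is_new) {
          dest$discovered_by <- "perturbation"
          dest$support_count <- 0L
          pool[[key]] <- dest
        }
        trans[[length(trans) + 1L]] <- data.frame(
          source = i, node = nm, level = lv,
          destination = key, new_attractor = is_new)
      }
    }
  }
  keys <- names(pool)
  attractors <- structure(unname(pool), class = "continuous_attractor_set",
                          nodes = net$nodes)
  transitions <- do.call(rbind, c(trans, list(make.row.names = FALSE)))
  transitions$destination <- match(transitions$destination, keys)
  list(attractors = attractors, transitions = transitions)
}

# clamp `node` at `level` for `duration`, release, relax to steady state
pulse_and_relax <- function(net, params, x0, node, level, duration) {
  cl <- stats::setNames(level, node)
  x <- as_continuous_state(net, x0)
  x[node] <- level
  rhs <- make_rhs(net, params, as_clamp_set(net, cl, continuous = TRUE))
  sol <- deSolve::lsoda(y = x, times = c(0, duration), func = rhs,
                        rtol = 1e-10, atol = 1e-12)
  x1 <- pmin(pmax(sol[nrow(sol), net$nodes], 0), 1)  # pulse runs at gamma = 1
  x1[node] <- level
  relax(net, params, x1)
}

#' Attractor locations across a parameter grid
#'
#' Recomputes the steady-state location reached from each wild-type binary
#' attractor for every value of `h` or `gamma` on a grid.  Binary attractor
#' corners are h-independent (the sigmoid fixes 0 and 1 for every gain),
#' whereas the saturated steady level `f(omega)/gamma` moves with the decay
#' rate, so attractors are highly sensitive to `gamma` deviating from 1.
#'
#' @inheritParams relax
#' @param sweep_variable `"h"` or `"gamma"`.
#' @param grid positive parameter values to scan.
#' @param start_states named list (or matrix with named columns) of starting
#'   levels; defaults to the binary core attractors of the packaged model if
#'   `net` has the core nodes.
#' @return a long data.frame: `value`, `start`, `node`, `level`,
#'   `converged`.
#' @export
parameter_sweep <- function(net, params, sweep_variable = c("h", "gamma"),
                            grid, start_states = NULL) {
  assert_network(net)
  sweep_variable <- match.arg(sweep_variable)
  stopifnot(all(grid > 0))
  if (is.null(start_states)) {
    sig <- cell_type_signatures()
    if (!all(bcell_core_nodes %in% net$nodes))
      stop("supply start_states for networks without the core module",
           call. = FALSE)
    start_states <- lapply(rownames(sig), function(lb)
      make_state(net, sig[lb, ][sig[lb, ] == 1]))
    names(start_states) <- rownames(sig)
  }
  rows <- list()
  for (v in grid) {
    p <- params
    if (sweep_variable == "h")
      p$h[] <- v
    else
      p$gamma[] <- v
    for (snm in names(start_states)) {
      res <- relax(net, p, start_states[[snm]])
      rows[[length(rows) + 1L]] <- data.frame(
        value = v, start = snm, node = net$nodes,
        level = as.numeric(res$levels), converged = res$converged)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
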