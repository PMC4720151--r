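#' Label an attractor by its core activation pattern
#'
#' Matches the attractor's pattern over the six core master regulators
#' against the canonical cell-type signatures (see
#' [cell_type_signatures()]).  An exact match (within `tol` per node)
#' returns the plain label.  When a clamped core node forces exactly that
#' bit away from a signature but every freely evolving core bit matches, the
#' label gains a `-like` suffix (e.g. `[0,0,0,0,1,0]` under a Bach2 clamp is
#' `Naive-like`).  Anything else is `Other`.
#'
#' @param x a state: named vector covering the core nodes, a
#'   `continuous_attractor`, or a single-attractor entry of an
#'   `attractor_set`.
#' @param clamped character vector of clamped node names (their core bits
#'   are excluded from the signature match).
#' @param signatures signature matrix, by default [cell_type_signatures()].
#' @param tol per-node tolerance for a match (default 0.1; continuous
#'   attractor levels sit within integration tolerance of 0, 0.5 or 1).
#' @return a label string: `"Naive"`, `"GC"`, `"Mem"`, `"PC"`, a `-like`
#'   variant, or `"Other"`.
#' @examples
#' label_attractor(c(Bach2 = 1, Bcl6 = 0, Blimp1 = 0, Irf4 = 0,
#'                   Pax5 = 1, XBP1 = 0))
#' @export
label_attractor <- function(x, clamped = character(),
                            signatures = cell_type_signatures(), tol = 0.1) {
  if (inherits(x, "continuous_attractor")) x <- x$levels
  if (is.list(x) && !is.null(x$states)) x <- x$states[, 1]
  core <- core_pattern(x)
  free <- setdiff(colnames(signatures), clamped)
  exact <- character()
  like <- character()
  for (lb in rownames(signatures)) {
    d <- abs(core - signatures[lb, names(core)])
    if (all(d <= tol)) exact <- c(exact, lb)
    else if (length(free) < length(core) && all(d[free] <= tol))
      like <- c(like, paste0(lb, "-like"))
  }
  if (length(exact) > 1L)
    stop("ambiguous label: core pattern matches ",
         paste(exact, collapse = " and "), call. = FALSE)
  if (length(exact) == 1L) return(exact)
  if (length(like) >= 1L) return(like[1L])
  "Other"
}

#' Attach cell-type labels to an attractor set
#'
#' @param aset an `attractor_set` or `continuous_attractor_set`.
#' @param clamped clamped node names, see [label_attractor()].
#' @param ... passed to [label_attractor()].
#' @return the set with `label` filled in on every attractor.
#' @export
label_attractors <- function(aset, clamped = character(), ...) {
  for (i in seq_along(aset)) {
    st <- if (inherits(aset, "continuous_attractor_set"))
      aset[[i]]$levels else aset[[i]]$states[, 1]
    aset[[i]]$label <- label_attractor(st, clamped = clamped, ...)
  }
  aset
}

#' A transient pulse of an extracellular signal
#'
#' During `[t_on, t_on + duration)` the node's level is pinned at `level`
#' and its derivative suppressed; afterwards the node re-enters free
#' dynamics.  A saturating pulse of two or more time units of the right
#' signal is enough to move the system between attractors (e.g. IL4 from
#' Naive to GC).
#'
#' @param node node name.
#' @param level pinned level in `[0, 1]` (default 1, a saturating signal).
#' @param t_on onset time.
#' @param duration pulse length, `> 0` (default 10).
#' @return a `pulse_event` object.
#' @export
pulse_event <- function(node, level = 1, t_on = 0, duration = 10) {
  stopifnot(length(node) == 1L, duration > 0, level >= 0, level <= 1,
            t_on >= 0)
  structure(list(node = node, level = level, t_on = t_on,
                 duration = duration), class = "pulse_event")
}

#' Pulse-driven differentiation simulation
#'
#' Starts at a converged attractor, applies a sequence of transient signal
#' pulses, integrates the continuous system with pinned levels during each
#' pulse window, relaxes after the last pulse, and reports the full
#' trajectory plus the destination attractor.  The canonical protocol
#' Naive -(IL4)-> GC -(CD40L)-> Mem -(Ag)-> PC reproduces the directional
#' differentiation sequence.
#'
#' @inheritParams relax
#' @param start named vector of starting levels (a converged attractor).
#' @param pulses list of [pulse_event()]s; onsets must be non-overlapping
#'   per node and are sorted by `t_on`.
#' @param record_dt sampling interval of the recorded trajectory.
#' @return list with `times`, `states` (time x node matrix), `events`, and
#'   `final` (the destination `continuous_attractor`), plus `final_label`
#'   when the network carries the core module.  Class `pulse_trajectory`.
#' @export
simulate_pulses <- function(net, params, start, pulses, record_dt = 0.5) {
  assert_network(net)
  if (inherits(pulses, "pulse_event")) pulses <- list(pulses)
  stopifnot(all(vapply(pulses, inherits, NA, "pulse_event")))
  ord <- order(vapply(pulses, `[[`, 0, "t_on"))
  pulses <- pulses[ord]
  x <- as_continuous_state(net, start)
  times <- 0
  states <- matrix(x, nrow = 1, dimnames = list(NULL, net$nodes))
  t_now <- 0
  integrate_to <- function(x, t0, t1, cl) {
    if (t1 <= t0) return(list(x = x, times = numeric(0), states = NULL))
    grid <- unique(c(seq(t0, t1, by = record_dt), t1))
    rhs <- make_rhs(net, params, cl)
    sol <- deSolve::lsoda(y = x, times = grid, func = rhs,
                          rtol = 1e-10, atol = 1e-12)
    list(x = sol[nrow(sol), net$nodes],
         times = sol[-1, "time"],
         states = sol[-1, net$nodes, drop = FALSE])
  }
  empty <- stats::setNames(numeric(0), character(0))
  for (p in pulses) {
    if (p$t_on < t_now)
      stop("overlapping pulses (onset ", p$t_on, " before ", t_now, ")",
           call. = FALSE)
    seg <- integrate_to(x, t_now, p$t_on, empty)
    if (!is.null(seg$states)) {
      times <- c(times, seg$times); states <- rbind(states, seg$states)
    }
    x <- seg$x
    cl <- as_clamp_set(net, stats::setNames(p$level, p$node),
                       continuous = TRUE)
    x[p$node] <- p$level
    seg <- integrate_to(x, p$t_on, p$t_on + p$duration, cl)
    if (!is.null(seg$states)) {
      times <- c(times, seg$times); states <- rbind(states, seg$states)
    }
    x <- seg$x
    x[p$node] <- p$level
    t_now <- p$t_on + p$duration
  }
  # record a settling window, then relax to convergence
  seg <- integrate_to(x, t_now, t_now + 25, empty)
  if (!is.null(seg$states)) {
    times <- c(times, seg$times); states <- rbind(states, seg$states)
  }
  final <- relax(net, params, pmin(pmax(seg$x, 0), 1))
  out <- list(times = times, states = states, events = pulses,
              final = final)
  if (all(bcell_core_nodes %in% net$nodes))
    out$final_label <- label_attractor(final)
  structure(out, class = "pulse_trajectory")
}

#' @export
print.pulse_trajectory <- function(x, ...) {
  cat("Pulse trajectory:", length(x$times), "samples over t = [0,",
      max(x$times), "],", length(x$events), "pulse(s)\n")
  for (p in x$events)
    cat(sprintf("  %s = %g during [%g, %g)\n", p$node, p$level, p$t_on,
                p$t_on + p$duration))
  if (!is.null(x$final_label)) cat("  destination:", x$final_label, "\n")
  invisible(x)
}

#' Trajectory heatmap (time x node activation levels)
#'
#' @param x a `pulse_trajectory`.
#' @param ... passed to [graphics::image()].
#' @export
plot.pulse_trajectory <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  graphics::image(x = x$times, y = seq_len(ncol(x$states)),
                  z = x$states, zlim = c(0, 1), col = pal,
                  xlab = "time (arbitrary units)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(ncol(x$states)),
                 labels = colnames(x$states), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Tidy trajectory export
#'
#' @param traj a `pulse_trajectory`.
#' @return data.frame with columns `time`, `node`, `level`.
#' @export
trajectory_frame <- function(traj) {
  data.frame(time = rep(traj$times, times = ncol(traj$states)),
             node = rep(colnames(traj$states), each = length(traj$times)),
             level = as.vector(traj$states))
}

#' Build the cell-fate map of a network
#'
#' The fate map is a directed graph whose vertices are the model's
#' attractors and whose edges are the single-node transient perturbations
#' that move the system from one attractor to another.  In discrete mode a
#' perturbation is a single-node bit flip (or set to `level`) applied to the
#' attractor state for one synchronous step, followed by free evolution; in
#' continuous mode the node is clamped at each level for `duration` time
#' units, released and relaxed.
#'
#' @inheritParams relax
#' @param engine `"discrete"` or `"continuous"`.
#' @param attractors the attractor set to map.  Discrete: an
#'   `attractor_set` (default: exhaustive enumeration).  Continuous: a
#'   `continuous_attractor_set` (required; e.g. the union found by
#'   [sample_attractors()] + [perturbation_search()]).
#' @param levels perturbation levels (default `0:1` discrete,
#'   `c(0, 0.5, 1)` continuous).
#' @param duration continuous clamp duration (default 10).
#' @return a `fate_map`: list with `vertices` (data.frame: id, label, core
#'   pattern) and `edges` (data.frame: source, target, node, level; only
#'   transitions with destination != source).
#' @export
build_fate_map <- function(net, params = NULL,
                           engine = c("discrete", "continuous"),
                           attractors = NULL, levels = NULL, duration = 10) {
  assert_network(net)
  engine <- match.arg(engine)
  has_core <- all(bcell_core_nodes %in% net$nodes)
  if (engine == "discrete") {
    if (is.null(levels)) levels <- c(0, 1)
    if (is.null(attractors)) attractors <- enumerate_attractors(net)
    if (has_core) attractors <- label_attractors(attractors)
    base_states <- lapply(attractors, function(a) a$states[, 1])
    match_dest <- function(states) {
      key <- paste(states[, 1], collapse = "")
      keys <- vapply(base_states, paste, "", collapse = "")
      m <- match(key, keys)
      if (is.na(m)) NA_integer_ else m
    }
    edges <- list()
    for (i in seq_along(base_states)) {
      for (nm in net$nodes) {
        for (lv in levels) {
          s <- base_states[[i]]
          if (s[nm] == lv) next                     # no-op perturbation
          s[nm] <- lv
          dest <- match_dest(find_attractor(net, s)$states)
          if (!is.na(dest) && dest != i)
            edges[[length(edges) + 1L]] <- data.frame(
              source = i, target = dest, node = nm, level = lv)
        }
      }
    }
  } else {
    if (is.null(levels)) levels <- c(0, 0.5, 1)
    if (is.null(attractors))
      stop("continuous fate map needs a precomputed attractor set ",
           "(sample_attractors + perturbation_search)", call. = FALSE)
    if (is.null(params)) stop("params required for the continuous engine",
                              call. = FALSE)
    if (has_core) attractors <- label_attractors(attractors)
    keys <- vapply(attractors, function(a)
      level_key(a$levels, params$merge_tol), "")
    edges <- list()
    for (i in seq_along(attractors)) {
      src_levels <- snap_levels(attractors[[i]]$levels, params$merge_tol)
      for (nm in net$nodes) {
        for (lv in levels) {
          if (abs(src_levels[nm] - lv) < params$merge_tol)
            next                                    # no-op perturbation
          dest <- pulse_and_relax(net, params, src_levels,
                                  nm, lv, duration)
          if (!dest$converged) next
          m <- match(level_key(dest$levels, params$merge_tol), keys)
          if (!is.na(m) && m != i)
            edges[[length(edges) + 1L]] <- data.frame(
              source = i, target = m, node = nm, level = lv)
        }
      }
    }
  }
  labels <- make.unique(vapply(seq_along(attractors), function(i) {
    lb <- attractors[[i]]$label
    if (is.null(lb) || is.na(lb)) paste0("A", i) else lb
  }, ""), sep = ".")
  core <- if (has_core)
    vapply(attractors, function(a) {
      st <- if (!is.null(a$levels)) a$levels else a$states[, 1]
      paste(round(core_pattern(st), 2), collapse = ",")
    }, "")
  else NA_character_
  vertices <- data.frame(id = seq_along(attractors), label = labels,
                         core = core)
  edges <- if (length(edges) > 0L)
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  else data.frame(source = integer(), target = integer(),
                  node = character(), level = numeric())
  structure(list(vertices = vertices, edges = edges, engine = engine,
                 levels = levels, duration = duration),
            class = "fate_map")
}

#' @export
print.fate_map <- function(x, ...) {
  cat("Fate map (", x$engine, " engine): ", nrow(x$vertices),
      " attractors, ", nrow(x$edges), " transition(s)\n", sep = "")
  if (nrow(x$edges) > 0L) {
    lab <- x$vertices$label
    sym <- ifelse(x$edges$level == 0, "-",
                  ifelse(x$edges$level == 1, "+", "int"))
    for (r in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -[%s%s]-> %s\n", lab[x$edges$source[r]],
                  x$edges$node[r], sym[r], lab[x$edges$target[r]]))
  }
  invisible(x)
}

#' Out-degree of a fate-map vertex
#'
#' @param fmap a `fate_map`.
#' @param label vertex label (e.g. `"PC"`).
#' @return integer number of outgoing transitions.
#' @export
fate_map_outdegree <- function(fmap, label) {
  id <- fmap$vertices$id[fmap$vertices$label == label]
  if (length(id) == 0L) stop("no vertex labelled '", label, "'", call. = FALSE)
  sum(fmap$edges$source %in% id)
}

#' Single-node mutant scan report
#'
#' Clamps every requested node at 0 and at 1 (loss- and gain-of-function)
#' and reports the labelled attractor set of each mutant: exhaustively for
#' the discrete engine, by random-start sampling for the continuous engine.
#' The clamped node is excluded from the signature match, giving the
#' `-like` labels of partially preserved fates.
#'
#' @inheritParams relax
#' @param nodes nodes to scan (default: all nodes, covering the regulatory
#'   core, the signalling cascades and sustained environmental signals).
#' @param values clamp values (default `c(0, 1)`).
#' @param engine `"discrete"`, `"continuous"` or `"both"`.
#' @param n_runs continuous random starts per mutant (default 500).
#' @param seed RNG seed for the continuous sampling.
#' @return a data.frame keyed by (node, value, engine) with one row per
#'   attractor: core pattern string, label, basin fraction (discrete) or
#'   support count (continuous).
#' @export
mutant_report <- function(net, params = NULL, nodes = net$nodes,
                          values = c(0, 1),
                          engine = c("discrete", "continuous", "both"),
                          n_runs = 500, seed = NULL) {
  assert_network(net)
  engine <- match.arg(engine)
  engines <- if (engine == "both") c("discrete", "continuous") else engine
  if ("continuous" %in% engines && is.null(params))
    stop("params required for the continuous engine", call. = FALSE)
  has_core <- all(bcell_core_nodes %in% net$nodes)
  rows <- list()
  for (nm in nodes) {
    for (v in values) {
      for (eng in engines) {
        if (eng == "discrete") {
          aset <- mutant_attractors(net, nm, v)
          if (has_core) aset <- label_attractors(aset, clamped = nm)
          for (i in seq_along(aset)) {
            st <- aset[[i]]$states[, 1]
            rows[[length(rows) + 1L]] <- data.frame(
              node = nm, value = v, engine = eng, attractor = i,
              core = if (has_core)
                paste(core_pattern(st), collapse = ",") else NA,
              label = if (has_core) aset[[i]]$label else NA,
              cycle_length = aset[[i]]$length,
              basin_fraction = aset[[i]]$basin_fraction,
              support = NA_real_)
          }
        } else {
          sub_seed <- if (is.null(seed)) NULL
            else (seed + 7L * match(nm, net$nodes) + as.integer(v)) %% .Machine$integer.max
          aset <- sample_attractors(net, params, n_runs = n_runs,
                                    seed = sub_seed,
                                    clamps = stats::setNames(v, nm))
          if (has_core) aset <- label_attractors(aset, clamped = nm)
          for (i in seq_along(aset)) {
            rows[[length(rows) + 1L]] <- data.frame(
              node = nm, value = v, engine = eng, attractor = i,
              core = if (has_core)
                paste(round(core_pattern(aset[[i]]$levels), 2),
                      collapse = ",") else NA,
              label = if (has_core) aset[[i]]$label else NA,
              cycle_length = 1L,
              basin_fraction = NA_real_,
              support = aset[[i]]$support_count)
          }
        }
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group a mutant scan by effect class
#'
#' Compares each mutant's labelled attractor set against the wild type and
#' assigns a qualitative effect: fates lost, fates replaced by `-like`
#' variants, atypical (`Other`) attractors found, or collapse to a single
#' attractor.
#'
#' @param report output of [mutant_report()] (one engine).
#' @param wild_type_labels labels of the wild-type attractors (default the
#'   four cell types).
#' @return data.frame keyed by (node, value) with columns `labels` and
#'   `effect`.
#' @export
mutant_summary <- function(report,
                           wild_type_labels = c("Naive", "GC", "Mem", "PC")) {
  key <- interaction(report$node, report$value, drop = TRUE)
  rows <- lapply(split(report, key), function(d) {
    labs <- unique(d$label)
    plain <- sub("-like$", "", labs)
    lost <- setdiff(wild_type_labels, plain)
    effects <- character()
    if (length(labs) == 1L)
      effects <- c(effects, paste("only the", labs, "attractor is found"))
    if (length(lost) > 0L)
      effects <- c(effects, paste("loss of", paste(lost, collapse = ", "),
                                  "attractor(s)"))
    if (any(grepl("-like$", labs)))
      effects <- c(effects, "fate(s) replaced by -like variant(s)")
    if ("Other" %in% labs)
      effects <- c(effects, "atypical attractor found")
    if (length(effects) == 0L) effects <- "wild-type fates preserved"
    data.frame(node = d$node[1], value = d$value[1],
               labels = paste(sort(labs), collapse = ";"),
               effect = paste(effects, collapse = "; "))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$node, out$value), , drop = FALSE]
}
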