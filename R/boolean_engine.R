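#' Encode / decode Boolean states as integers
#'
#' States are encoded under the network's fixed node order: the first node is
#' bit 0, the second bit 1, and so on.  The encoding is bijective with the
#' bit map, which makes attractor tables and basin counts reproducible.
#'
#' @param net a [regulatory_network].
#' @param state a named 0/1 vector over all nodes.
#' @param code a non-negative integer below `2^n_nodes(net)`.
#' @return `encode_state()` returns a double (exact for up to 52 nodes);
#'   `decode_state()` returns a named integer vector.
#' @export
encode_state <- function(net, state) {
  s <- as_boolean_state(net, state)
  sum(s * 2^(seq_along(s) - 1))
}

#' @rdname encode_state
#' @export
decode_state <- function(net, code) {
  n <- length(net$nodes)
  stopifnot(code >= 0, code < 2^n)
  bits <- as.integer(floor(code / 2^(0:(n - 1))) %% 2)
  names(bits) <- net$nodes
  bits
}

#' One synchronous Boolean update
#'
#' Every non-input, non-clamped node is set by its rule evaluated on the old
#' state; input nodes decay to 0 unless clamped; clamped nodes keep their
#' clamp value.  All nodes update simultaneously.
#'
#' @param net a [regulatory_network].
#' @param state named 0/1 vector over all nodes.
#' @param clamps optional named 0/1 vector of permanently fixed nodes
#'   (empty = wild type).
#' @return the successor state, named integer 0/1 in node order.
#' @examples
#' net <- load_bcell_network()
#' naive <- make_state(net, c("Bach2", "Pax5"))
#' identical(boolean_step(net, naive), as_boolean_state(net, naive))
#' @export
boolean_step <- function(net, state, clamps = NULL) {
  assert_network(net)
  s <- as_boolean_state(net, state)
  cl <- as_clamp_set(net, clamps)
  env <- as.list(s == 1L)
  nxt <- integer(length(s))
  names(nxt) <- net$nodes
  for (nm in net$nodes) {
    nxt[nm] <- if (nm %in% names(cl)) as.integer(cl[[nm]])
               else if (nm %in% net$inputs) 0L
               else as.integer(isTRUE(eval(net$rules[[nm]], env, baseenv())))
  }
  nxt
}

#' Follow one trajectory to its attractor
#'
#' Iterates the synchronous update from `state`, hashing visited states,
#' until a state recurs.  The finite state space guarantees termination.
#'
#' @inheritParams boolean_step
#' @return a list with `states` (node x cycle-length 0/1 matrix; one column
#'   for a fixed point), `length` (cycle length) and `transient`
#'   (steps before entering the cycle).
#' @examples
#' toggle <- regulatory_network(list(A = "!B", B = "!A"))
#' find_attractor(toggle, c(A = 0, B = 0))$length  # synchronous 2-cycle
#' @export
find_attractor <- function(net, state, clamps = NULL) {
  assert_network(net)
  s <- as_boolean_state(net, state)
  cl <- as_clamp_set(net, clamps)
  if (length(cl) > 0L) s[names(cl)] <- as.integer(cl)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- list()
  k <- 0L
  repeat {
    key <- paste(s, collapse = "")
    hit <- get0(key, envir = seen)
    if (!is.null(hit)) {
      cyc <- path[(hit + 1L):k]
      m <- do.call(cbind, cyc)
      rownames(m) <- net$nodes
      colnames(m) <- NULL
      return(list(states = canonical_cycle(m), length = ncol(m),
                  transient = hit))
    }
    assign(key, k, envir = seen)
    k <- k + 1L
    path[[k]] <- s
    s <- boolean_step(net, s, clamps = cl)
  }
}

# rotate a cycle matrix so the lexicographically smallest encoded state
# comes first: makes attractor identity independent of entry point
canonical_cycle <- function(m) {
  codes <- colSums(m * 2^(seq_len(nrow(m)) - 1))
  i <- which.min(codes)
  if (i > 1L) m <- m[, c(i:ncol(m), seq_len(i - 1L)), drop = FALSE]
  m
}

#' Exhaustive synchronous attractor enumeration with exact basins
#'
#' Visits every initial state of the free nodes (all nodes minus clamped
#' ones), computes the full synchronous successor map bit-parallel, and
#' resolves every trajectory by pointer doubling.  Returns all distinct
#' attractors (fixed points and limit cycles) with exact basin counts;
#' `basin_fraction = basin_count / 2^(free nodes)` so fractions always sum
#' to 1.
#'
#' The successor map is materialised in memory, so enumeration is refused
#' beyond `max_free` free nodes (default 24, about 1.5 GB of working set).
#'
#' @inheritParams boolean_step
#' @param max_free refusal guard on the number of free nodes.
#' @return an object of class `attractor_set`: a list of attractors, each
#'   with `states`, `length`, `basin_count`, `basin_fraction` and `label`
#'   (NA until [label_attractors()] is applied), sorted by decreasing basin;
#'   attributes record the network nodes, clamps and state-space size.
#' @examples
#' \donttest{
#' aset <- enumerate_attractors(load_bcell_network())
#' length(aset)  # 4 fixed points
#' }
#' @export
enumerate_attractors <- function(net, clamps = NULL, max_free = 24L) {
  assert_network(net)
  cl <- as_clamp_set(net, clamps)
  free <- setdiff(net$nodes, names(cl))
  nf <- length(free)
  if (nf > max_free)
    stop("exhaustive enumeration refused: ", nf, " free nodes exceed the ",
         max_free, "-node guard (2^", nf, " states); clamp nodes or raise ",
         "'max_free'", call. = FALSE)
  N <- 2^nf
  bit <- 2^(seq_len(nf) - 1)
  states <- 0:(N - 1)
  env <- new.env(parent = baseenv())
  for (j in seq_len(nf))
    assign(free[j], bitwAnd(states, as.integer(bit[j])) != 0L, envir = env)
  for (nm in names(cl))
    assign(nm, rep(cl[[nm]] != 0, N), envir = env)
  # synchronous successor of every state, encoded over the free bits only
  succ <- numeric(N)
  for (j in seq_len(nf)) {
    nm <- free[j]
    if (nm %in% net$inputs) next                     # inputs decay to 0
    succ <- succ + bit[j] * eval(net$rules[[nm]], env)
  }
  rm(env)
  s1 <- as.integer(succ) + 1L
  # pointer doubling: after ceiling(log2(N)) + 1 squarings every state has
  # been advanced >= N steps, i.e. onto its attractor cycle
  landed <- s1
  for (k in seq_len(nf + 1L)) landed <- landed[landed]
  on_cycle <- unique(landed)
  # trace each cycle once; canonical representative = smallest member
  rep_of <- integer(length(on_cycle))
  cycles <- vector("list", length(on_cycle))
  traced <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(on_cycle)) {
    x <- on_cycle[i]
    known <- get0(as.character(x), envir = traced)
    if (!is.null(known)) { rep_of[i] <- known; next }
    cyc <- x
    y <- s1[x]
    while (y != x) { cyc <- c(cyc, y); y <- s1[y] }
    r <- min(cyc)
    for (z in cyc) assign(as.character(z), r, envir = traced)
    rep_of[i] <- r
    cycles[[i]] <- cyc
  }
  basin <- tapply(rep(1L, N), rep_of[match(landed, on_cycle)], sum)
  reps <- as.integer(names(basin))
  # decode attractor cycles in deterministic synchronous order
  out <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    cyc <- reps[i]
    y <- s1[reps[i]]
    while (y != reps[i]) { cyc <- c(cyc, y); y <- s1[y] }
    m <- matrix(0L, nrow = length(net$nodes), ncol = length(cyc),
                dimnames = list(net$nodes, NULL))
    for (k in seq_along(cyc)) {
      code <- cyc[k] - 1L
      m[free, k] <- as.integer(bitwAnd(code, as.integer(bit)) != 0L)
    }
    if (length(cl) > 0L) m[names(cl), ] <- as.integer(cl)
    out[[i]] <- list(states = m, length = ncol(m),
                     basin_count = as.numeric(basin[i]),
                     basin_fraction = as.numeric(basin[i]) / N,
                     label = NA_character_)
  }
  out <- out[order(-vapply(out, `[[`, 0, "basin_count"))]
  structure(out, class = "attractor_set",
            nodes = net$nodes, clamps = cl, n_free = nf, n_states = N)
}

#' Attractors of a single-node mutant
#'
#' Loss-of-function (`fixed_value = 0`) or gain-of-function
#' (`fixed_value = 1`) mutants are modelled by clamping one node and
#' re-running the exhaustive enumeration; the clamped bit is fixed in every
#' reported state.
#'
#' @inheritParams enumerate_attractors
#' @param node node to clamp.
#' @param fixed_value 0 (null mutant) or 1 (constitutive mutant).
#' @return an `attractor_set` (see [enumerate_attractors()]).
#' @export
mutant_attractors <- function(net, node, fixed_value, max_free = 24L) {
  stopifnot(length(node) == 1L)
  if (!node %in% net$nodes)
    stop("unknown node: ", node, call. = FALSE)
  enumerate_attractors(net, clamps = stats::setNames(fixed_value, node),
                       max_free = max_free)
}

#' @export
print.attractor_set <- function(x, ...) {
  cl <- attr(x, "clamps")
  cat("Attractor set:", length(x), "attractor(s) over",
      format(attr(x, "n_states"), big.mark = ","), "states")
  if (length(cl) > 0L)
    cat(" [clamped: ", paste(names(cl), "=", cl, collapse = ", "), "]", sep = "")
  cat("\n")
  for (i in seq_along(x)) {
    a <- x[[i]]
    on <- rownames(a$states)[a$states[, 1] == 1]
    cat(sprintf("  %d. %s basin %.4f%%  {%s}%s\n", i,
                if (a$length == 1L) "fixed point" else paste0(a$length, "-cycle"),
                100 * a$basin_fraction,
                paste(on, collapse = ","),
                if (is.na(a$label)) "" else paste0("  [", a$label, "]")))
  }
  invisible(x)
}

#' Tidy data frame of an attractor set
#'
#' One row per attractor state (fixed points contribute one row, cycles one
#' per phase), with the full bit pattern, the core-module pattern when the
#' network has the six core nodes, basin statistics and label.
#'
#' @param x an `attractor_set`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return a data.frame.
#' @export
as.data.frame.attractor_set <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  nodes <- attr(x, "nodes")
  has_core <- all(bcell_core_nodes %in% nodes)
  rows <- list()
  for (i in seq_along(x)) {
    a <- x[[i]]
    for (k in seq_len(a$length)) {
      st <- a$states[, k]
      rows[[length(rows) + 1L]] <- data.frame(
        attractor = i, phase = k, length = a$length,
        pattern = paste(st, collapse = ""),
        core = if (has_core) paste(core_pattern(st), collapse = "") else NA,
        basin_count = a$basin_count,
        basin_fraction = a$basin_fraction,
        label = a$label)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
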