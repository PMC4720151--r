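# Independent brute-force oracle for the synchronous Boolean dynamics.
# Deliberately shares no code path with the package engine: its own
# recursive AST walker (no eval()), a per-state trajectory follower with a
# visited list (no bit-parallel successor map, no pointer doubling).

oracle_eval <- function(expr, state) {
  if (is.symbol(expr)) {
    v <- state[[as.character(expr)]]
    return(v != 0)
  }
  if (is.numeric(expr) || is.logical(expr)) return(expr != 0)
  op <- as.character(expr[[1]])
  if (op == "(") return(oracle_eval(expr[[2]], state))
  if (op == "!") return(!oracle_eval(expr[[2]], state))
  if (op %in% c("&", "&&"))
    return(oracle_eval(expr[[2]], state) && oracle_eval(expr[[3]], state))
  if (op %in% c("|", "||"))
    return(oracle_eval(expr[[2]], state) || oracle_eval(expr[[3]], state))
  stop("oracle: unknown operator ", op)
}

oracle_step <- function(net, state, clamps = NULL) {
  out <- state
  for (nm in net$nodes) {
    out[nm] <- if (!is.null(clamps) && nm %in% names(clamps))
      as.integer(clamps[[nm]])
    else if (nm %in% net$inputs) 0L
    else as.integer(oracle_eval(net$rules[[nm]], state))
  }
  out
}

# exhaustive attractor search by following every trajectory individually;
# returns a list keyed by canonical attractor id with `states` (matrix) and
# `basin` (count). Only for small networks (<= 14 free nodes).
oracle_attractors <- function(net, clamps = NULL) {
  free <- setdiff(net$nodes, names(clamps))
  nf <- length(free)
  stopifnot(nf <= 14)
  res <- list()
  for (i in 0:(2^nf - 1)) {
    s <- stats::setNames(integer(length(net$nodes)), net$nodes)
    s[free] <- as.integer(bitwAnd(i, 2^(seq_len(nf) - 1)) != 0)
    if (!is.null(clamps)) s[names(clamps)] <- as.integer(clamps)
    seen <- character()
    repeat {
      key <- paste(s, collapse = "")
      pos <- match(key, seen)
      if (!is.na(pos)) {
        cyc_keys <- seen[pos:length(seen)]
        canon <- min(cyc_keys)
        if (is.null(res[[canon]])) {
          m <- matrix(unlist(lapply(cyc_keys, function(k)
            as.integer(strsplit(k, "")[[1]]))),
            nrow = length(net$nodes),
            dimnames = list(net$nodes, NULL))
          res[[canon]] <- list(states = m, basin = 0L)
        }
        res[[canon]]$basin <- res[[canon]]$basin + 1L
        break
      }
      seen <- c(seen, key)
      s <- oracle_step(net, s, clamps)
    }
  }
  res
}

# canonical fingerprint of an attractor: sorted set of full-state strings
attractor_fingerprint <- function(states_matrix) {
  paste(sort(apply(states_matrix, 2, paste, collapse = "")), collapse = "/")
}

# compare an engine attractor_set with the oracle: same attractors, same
# cycle lengths, same basin counts
expect_matches_oracle <- function(aset, oracle) {
  eng <- lapply(aset, function(a) list(
    fp = attractor_fingerprint(a$states), basin = a$basin_count,
    len = a$length))
  orc <- lapply(oracle, function(a) list(
    fp = attractor_fingerprint(a$states), basin = as.numeric(a$basin),
    len = ncol(a$states)))
  eng <- unname(eng[order(vapply(eng, `[[`, "", "fp"))])
  orc <- unname(orc[order(vapply(orc, `[[`, "", "fp"))])
  expect_identical(lapply(eng, `[[`, "fp"), lapply(orc, `[[`, "fp"))
  expect_identical(lapply(eng, `[[`, "basin"), lapply(orc, `[[`, "basin"))
  expect_identical(lapply(eng, `[[`, "len"), lapply(orc, `[[`, "len"))
}
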