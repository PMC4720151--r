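#' Construct a qualitative regulatory network
#'
#' A regulatory network couples a set of named nodes with one logic rule per
#' non-input node.  Input (regulator-free) nodes carry no rule; in the
#' discrete engine they decay to 0 unless clamped, and in the continuous
#' engine their equation contains only the decay term.
#'
#' Node order is fixed (byte-wise alphabetical) at construction so that state
#' encodings, attractor tables and file exports are reproducible regardless
#' of declaration order or locale.
#'
#' @param rules named list mapping each non-input node to its rule: a string
#'   such as `"A & !B"` or an expression (see [as_rule()]).
#' @param inputs character vector of input node names (no rule allowed).
#' @param categories optional named character vector assigning each node one
#'   of `"core"`, `"signalling"` or `"environment"`; unspecified nodes
#'   default to `"signalling"` (inputs to `"environment"`).
#' @return an object of class `regulatory_network` with elements `nodes`
#'   (ordered character vector), `rules` (named list of expressions, ruled
#'   nodes only), `inputs` and `categories`.
#' @examples
#' toggle <- regulatory_network(list(A = "!B", B = "!A"))
#' toggle$nodes
#' @export
regulatory_network <- function(rules, inputs = character(), categories = NULL) {
  if (length(rules) > 0L && (is.null(names(rules)) || any(names(rules) == "")))
    stop("every rule must be named after its target node", call. = FALSE)
  if (anyDuplicated(names(rules)))
    stop("duplicate rule for node(s): ",
         paste(unique(names(rules)[duplicated(names(rules))]), collapse = ", "),
         call. = FALSE)
  if (any(inputs %in% names(rules)))
    stop("input node(s) cannot carry a rule: ",
         paste(intersect(inputs, names(rules)), collapse = ", "), call. = FALSE)
  rules <- lapply(rules, as_rule)
  nodes <- sort(unique(c(names(rules), inputs)), method = "radix")
  if (any(nodes == ""))
    stop("node names must be non-empty", call. = FALSE)
  # every referenced literal must be a declared node
  for (tgt in names(rules)) {
    refs <- unique(rule_literals(rules[[tgt]])$node)
    unknown <- setdiff(refs, nodes)
    if (length(unknown) > 0L)
      stop("rule for '", tgt, "' references undeclared node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  cats <- rep("signalling", length(nodes))
  names(cats) <- nodes
  cats[inputs] <- "environment"
  if (!is.null(categories)) {
    bad <- setdiff(names(categories), nodes)
    if (length(bad) > 0L)
      stop("categories given for unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    stopifnot(all(categories %in% c("core", "signalling", "environment")))
    cats[names(categories)] <- categories
  }
  structure(
    list(nodes = nodes,
         rules = rules[intersect(nodes, names(rules))],
         inputs = sort(inputs, method = "radix"),
         categories = cats),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", length(x$nodes), "nodes (",
      length(x$rules), "ruled,", length(x$inputs), "input )\n")
  for (nm in x$nodes) {
    if (nm %in% x$inputs)
      cat("  ", nm, " <- <input: decays to 0 unless clamped>\n", sep = "")
    else
      cat("  ", nm, " <- ", deparse_rule(x$rules[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Number of nodes in a network
#' @param net a `regulatory_network`.
#' @return integer.
#' @export
n_nodes <- function(net) length(net$nodes)

is_regulatory_network <- function(x) inherits(x, "regulatory_network")

assert_network <- function(net) {
  if (!is_regulatory_network(net))
    stop("expected a 'regulatory_network' object", call. = FALSE)
  invisible(net)
}

#' Extract the signed interaction list of a network
#'
#' Emits one signed regulator-to-target edge per distinct literal occurrence
#' in the target's rule, deduplicated.  The sign is positive when the
#' regulator appears un-negated.  A regulator appearing both negated and
#' un-negated in the same rule has no well-defined sign and raises an error
#' rather than guessing.
#'
#' @param net a `regulatory_network`.
#' @return a data.frame with columns `source`, `target` and `sign`
#'   (`"positive"`/`"negative"`), ordered by target then source.
#' @examples
#' net <- load_bcell_network()
#' nrow(extract_interactions(net))  # 39
#' @export
extract_interactions <- function(net) {
  assert_network(net)
  rows <- list()
  for (tgt in names(net$rules)) {
    lits <- rule_literals(net$rules[[tgt]])
    if (nrow(lits) == 0L) next
    per <- unique(lits)
    amb <- per$node[duplicated(per$node)]
    if (length(amb) > 0L)
      stop("ambiguous sign: node(s) ", paste(unique(amb), collapse = ", "),
           " appear both negated and un-negated in the rule for '", tgt, "'",
           call. = FALSE)
    rows[[tgt]] <- data.frame(
      source = per$node,
      target = tgt,
      sign = ifelse(per$negated, "negative", "positive"))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(source = character(), target = character(),
                      sign = character())
  out <- unique(out)
  out[order(out$target, out$source, method = "radix"), , drop = FALSE]
}

#' Coerce and validate a full Boolean state
#'
#' Checks that `state` assigns every node of the network and returns it as a
#' named integer 0/1 vector in the network's fixed node order.
#'
#' @param net a `regulatory_network`.
#' @param state named logical or 0/1 numeric vector over all nodes.
#' @return named integer vector in node order.
#' @export
as_boolean_state <- function(net, state) {
  if (is.null(names(state)))
    stop("state must be a named vector", call. = FALSE)
  missing <- setdiff(net$nodes, names(state))
  if (length(missing) > 0L)
    stop("state does not assign node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- as.integer(as.logical(state[net$nodes]))
  names(v) <- net$nodes
  v
}

# validate a clamp set: named vector, known nodes, 0/1 (discrete) or [0,1]
as_clamp_set <- function(net, clamps, continuous = FALSE) {
  if (is.null(clamps) || length(clamps) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(clamps)) || any(names(clamps) == ""))
    stop("clamps must be a named vector (node = level)", call. = FALSE)
  unknown <- setdiff(names(clamps), net$nodes)
  if (length(unknown) > 0L)
    stop("clamp on unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(clamps)
  names(v) <- names(clamps)
  if (continuous) {
    if (any(v < 0 | v > 1)) stop("clamp levels must lie in [0, 1]", call. = FALSE)
  } else {
    if (!all(v %in% c(0, 1))) stop("discrete clamps must be 0 or 1", call. = FALSE)
  }
  v
}

#' Build a state vector with selected nodes active
#'
#' Convenience constructor: a full 0 state in network node order with the
#' named nodes (or name = value pairs) switched on.
#'
#' @param net a `regulatory_network`.
#' @param active character vector of nodes to set to 1, or a named numeric
#'   vector of levels.
#' @return a named numeric vector over all nodes.
#' @examples
#' net <- load_bcell_network()
#' make_state(net, c("Bach2", "Pax5"))  # the Naive pattern
#' @export
make_state <- function(net, active = character()) {
  assert_network(net)
  s <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (length(active) > 0L) {
    if (is.character(active)) {
      unknown <- setdiff(active, net$nodes)
      if (length(unknown) > 0L)
        stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
      s[active] <- 1
    } else {
      unknown <- setdiff(names(active), net$nodes)
      if (length(unknown) > 0L)
        stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
      s[names(active)] <- as.numeric(active)
    }
  }
  s
}
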