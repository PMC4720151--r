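#' Generate a random Boolean network
#'
#' Produces a well-formed random network for engine testing: `n_inputs`
#' regulator-free nodes plus ruled nodes whose rules reference exactly
#' `in_degree` regulators drawn uniformly from all nodes.  Two rule styles
#' are available: random AND/OR/NOT expression trees with random literal
#' negation, or random truth tables materialised as disjunctive normal form
#' (so that every generated rule fuzzifies uniformly for the continuous
#' engine).  Generation is deterministic given `seed`.
#'
#' @param n_nodes total node count.
#' @param in_degree regulators per ruled node (scalar, `<= n_nodes`).
#' @param n_inputs number of regulator-free input nodes.
#' @param rule_style `"and_or_not_tree"` or `"truth_table_dnf"`.
#' @param seed optional RNG seed.
#' @return a [regulatory_network].
#' @examples
#' net <- generate_random_network(8, in_degree = 2, n_inputs = 1, seed = 7)
#' length(net$rules)  # 7
#' @export
generate_random_network <- function(n_nodes, in_degree = 2, n_inputs = 0,
                                    rule_style = c("and_or_not_tree",
                                                   "truth_table_dnf"),
                                    seed = NULL) {
  rule_style <- match.arg(rule_style)
  stopifnot(n_nodes >= 1, n_inputs >= 0, n_inputs < n_nodes)
  if (in_degree > n_nodes)
    stop("infeasible spec: in_degree ", in_degree, " exceeds n_nodes ",
         n_nodes, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  inputs <- if (n_inputs > 0) sample(nodes, n_inputs) else character()
  ruled <- setdiff(nodes, inputs)
  rules <- lapply(ruled, function(nm) {
    regs <- sample(nodes, in_degree)
    if (rule_style == "and_or_not_tree") random_tree_rule(regs)
    else random_dnf_rule(regs)
  })
  names(rules) <- ruled
  regulatory_network(rules, inputs = inputs)
}

# random binary AND/OR tree over the regulators, literals negated with
# probability 0.3
random_tree_rule <- function(regs) {
  lit <- function(nm) {
    s <- as.symbol(nm)
    if (stats::runif(1) < 0.3) call("!", s) else s
  }
  build <- function(v) {
    if (length(v) == 1L) return(lit(v))
    k <- sample(length(v) - 1L, 1L)
    op <- if (stats::runif(1) < 0.5) "&" else "|"
    call(op, build(v[seq_len(k)]), build(v[-seq_len(k)]))
  }
  build(sample(regs))
}

# random non-constant truth table over the regulators, written as a full
# disjunctive normal form (every minterm references every regulator)
random_dnf_rule <- function(regs) {
  k <- length(regs)
  repeat {
    tt <- stats::runif(2^k) < 0.5
    if (any(tt) && !all(tt)) break
  }
  minterm <- function(i) {
    bits <- as.integer(bitwAnd(i, 2^(seq_len(k) - 1)) != 0)
    lits <- mapply(function(nm, b) {
      s <- as.symbol(nm)
      if (b == 1L) s else call("!", s)
    }, regs, bits, SIMPLIFY = FALSE)
    Reduce(function(a, b) call("&", a, b), lits)
  }
  terms <- lapply(which(tt) - 1L, minterm)
  Reduce(function(a, b) call("|", a, b), terms)
}

#' Library of hand-built toy networks with known dynamics
#'
#' Small fixtures whose synchronous dynamics are fully enumerable by hand:
#' \describe{
#'   \item{toggle}{mutual inhibition `A <- !B`, `B <- !A`: fixed points
#'     (1,0) and (0,1), plus the synchronous 2-cycle (0,0) <-> (1,1).}
#'   \item{self_activator}{`A <- A`: fixed points 0 and 1.}
#'   \item{negative_ring}{3-node ring with one inhibition
#'     (`A <- !C, B <- A, C <- B`): no fixed point, synchronous cycles
#'     only.}
#'   \item{isolated_input}{a single regulator-free node: unique all-zero
#'     fixed point under the input-decay convention.}
#' }
#'
#' @return named list of [regulatory_network]s.
#' @export
toy_library <- function() {
  list(
    toggle = regulatory_network(list(A = "!B", B = "!A")),
    self_activator = regulatory_network(list(A = "A")),
    negative_ring = regulatory_network(list(A = "!C", B = "A", C = "B")),
    isolated_input = regulatory_network(list(), inputs = "A"))
}
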