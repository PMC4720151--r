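#' Logic rules as expression trees
#'
#' A logic rule is stored as an ordinary R expression over node-name symbols
#' and the operators `&` (AND), `|` (OR) and `!` (NOT).  Keeping the rule as
#' an explicit syntax tree (rather than a truth table) lets the same object
#' drive both the Boolean engine and, after [fuzzify_rule()], the continuous
#' engine.
#'
#' @param x a character string (e.g. `"Blimp1 & !Pax5"`) or an unevaluated
#'   R expression using only `&`, `|`, `!`, parentheses, node names and the
#'   constants `0`/`1`.
#' @return an unevaluated R call/symbol representing the rule.
#' @examples
#' r <- as_rule("Pax5 & !Blimp1")
#' eval_rule(r, c(Pax5 = 1, Blimp1 = 0))
#' @export
as_rule <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- tryCatch(str2lang(x),
                  error = function(e) stop("cannot parse rule: ", conditionMessage(e),
                                           call. = FALSE))
  }
  validate_rule_syntax(x)
  x
}

# allowed operator heads in a rule tree
.rule_ops <- c("&", "|", "!", "(", "&&", "||")

validate_rule_syntax <- function(expr) {
  if (is.symbol(expr)) return(invisible(TRUE))
  if (is.numeric(expr) || is.logical(expr)) {
    if (!(as.numeric(expr) %in% c(0, 1)))
      stop("rule constants must be 0 or 1", call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.call(expr)) {
    op <- as.character(expr[[1]])
    if (!op %in% .rule_ops)
      stop("operator '", op, "' not allowed in a logic rule ",
           "(use &, |, ! and parentheses)", call. = FALSE)
    for (i in seq_along(expr)[-1]) validate_rule_syntax(expr[[i]])
    return(invisible(TRUE))
  }
  stop("malformed rule expression", call. = FALSE)
}

#' @rdname as_rule
#' @export
is_rule <- function(x) {
  ok <- tryCatch({ validate_rule_syntax(x); TRUE }, error = function(e) FALSE)
  (is.symbol(x) || is.call(x) || is.numeric(x) || is.logical(x)) && ok
}

#' Nodes referenced by a rule
#'
#' Walks the rule tree and returns every literal occurrence together with its
#' sign: a literal is negative when it sits under an odd number of negations.
#'
#' @param rule a rule expression (see [as_rule()]).
#' @return a data.frame with columns `node` and `negated` (logical), one row
#'   per literal occurrence, in left-to-right order.
#' @export
rule_literals <- function(rule) {
  out <- list()
  walk <- function(e, neg) {
    if (is.symbol(e)) {
      out[[length(out) + 1L]] <<- list(node = as.character(e), negated = neg)
    } else if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "!") walk(e[[2]], !neg)
      else if (op == "(") walk(e[[2]], neg)
      else { walk(e[[2]], neg); if (length(e) > 2L) walk(e[[3]], neg) }
    }
    # numeric constants carry no literal
  }
  walk(rule, FALSE)
  if (length(out) == 0L)
    return(data.frame(node = character(), negated = logical()))
  data.frame(node = vapply(out, `[[`, "", "node"),
             negated = vapply(out, `[[`, NA, "negated"))
}

#' Evaluate a Boolean rule on a state
#'
#' Standard Boolean semantics of the rule tree: `x(t+1) = F(x_1(t), ...)`.
#' The evaluation is pure; the same state always yields the same output.
#'
#' @param rule a rule expression.
#' @param state a named vector (logical, or numeric 0/1) assigning a value to
#'   every node the rule references.
#' @return integer 0 or 1.
#' @examples
#' eval_rule(as_rule("Blimp1 & !Pax5"), c(Blimp1 = 1, Pax5 = 0))
#' @export
eval_rule <- function(rule, state) {
  lits <- unique(rule_literals(rule)$node)
  missing <- setdiff(lits, names(state))
  if (length(missing) > 0L)
    stop("state does not assign node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  env <- as.list(as.logical(state))
  names(env) <- names(state)
  as.integer(isTRUE(as.logical(eval(rule, env, baseenv()))))
}

#' Fuzzify a logic rule
#'
#' Structure-preserving conversion of a Boolean rule into its fuzzy-logic
#' counterpart: `A & B` becomes `min(A, B)`, `A | B` becomes `max(A, B)` and
#' `!A` becomes `1 - A`.  Restricted to 0/1 inputs the fuzzy expression
#' evaluates identically to the Boolean rule.
#'
#' @param rule a rule expression (see [as_rule()]).
#' @return an R expression over `min`, `max` and `1 - x`.
#' @examples
#' fuzzify_rule(as_rule("Pax5 & !Blimp1"))  # min(Pax5, 1 - Blimp1)
#' @export
fuzzify_rule <- function(rule) {
  f <- function(e) {
    if (is.symbol(e)) return(e)
    if (is.numeric(e) || is.logical(e)) return(as.numeric(e))
    op <- as.character(e[[1]])
    switch(op,
      "(" = f(e[[2]]),
      "!" = call("-", 1, f(e[[2]])),
      "&" = , "&&" = call("min", f(e[[2]]), f(e[[3]])),
      "|" = , "||" = call("max", f(e[[2]]), f(e[[3]])),
      stop("operator '", op, "' not allowed in a logic rule", call. = FALSE))
  }
  validate_rule_syntax(rule)
  f(rule)
}

#' Evaluate a fuzzified rule on continuous activation levels
#'
#' @param fuzzy an expression produced by [fuzzify_rule()].
#' @param levels named numeric vector of activation levels in `[0, 1]`.
#' @return a scalar in `[0, 1]`.
#' @export
eval_fuzzy <- function(fuzzy, levels) {
  as.numeric(eval(fuzzy, as.list(levels), baseenv()))
}

# deparse a rule back to BoolNet-style text (operators &, |, !)
deparse_rule <- function(rule) {
  paste(deparse(rule, width.cutoff = 500L), collapse = " ")
}
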