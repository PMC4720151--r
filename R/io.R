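#' Read a network from a BoolNet-style rule file
#'
#' The format is one `target, factors` line per node after a `targets,
#' factors` header; factors use the operators `&`, `|`, `!` and parentheses.
#' Input (regulator-free) nodes are declared with an empty factor or an
#' explicit `0`.  Lines starting with `#` and blank lines are ignored.
#' [write_boolnet()] followed by [read_boolnet()] is lossless.
#'
#' @param path file path.
#' @return a [regulatory_network].
#' @export
read_boolnet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("empty rule file: ", path, call. = FALSE)
  header <- keep[1]
  if (!grepl("^\\s*targets\\s*,\\s*factors\\s*$", lines[header],
             ignore.case = TRUE))
    stop("line ", header, ": expected header 'targets, factors'",
         call. = FALSE)
  rules <- list()
  inputs <- character()
  for (i in keep[-1]) {
    ln <- lines[i]
    m <- regexpr(",", ln, fixed = TRUE)
    if (m < 0)
      stop("line ", i, ": expected 'target, factors'", call. = FALSE)
    tgt <- trimws(substr(ln, 1L, m - 1L))
    fac <- trimws(substr(ln, m + 1L, nchar(ln)))
    if (tgt == "")
      stop("line ", i, ": empty target name", call. = FALSE)
    if (tgt %in% c(names(rules), inputs))
      stop("line ", i, ": duplicate target '", tgt, "'", call. = FALSE)
    if (fac == "" || fac == "0") {
      inputs <- c(inputs, tgt)
    } else {
      rules[[tgt]] <- tryCatch(as_rule(fac), error = function(e)
        stop("line ", i, ": ", conditionMessage(e), call. = FALSE))
    }
  }
  tryCatch(regulatory_network(rules, inputs = inputs),
           error = function(e)
             stop("invalid network in ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

#' @rdname read_boolnet
#' @param net a [regulatory_network].
#' @export
write_boolnet <- function(net, path) {
  assert_network(net)
  lines <- c("targets, factors",
             vapply(net$nodes, function(nm) {
               if (nm %in% net$inputs) paste0(nm, ", 0")
               else paste0(nm, ", ", deparse_rule(net$rules[[nm]]))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SBML-qual subset: qualitativeSpecies (maxLevel 1) + transitions whose
# single level-1 function term is a MathML and/or/not tree over eq(ci, 1)
# leaves.  Enough to mirror the packaged model; not a general SBML round
# trip.

sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
qual_ns <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
mathml_ns <- "http://www.w3.org/1998/Math/MathML"

#' Export a network to SBML-qual (subset)
#'
#' Writes each node as a `qual:qualitativeSpecies` with `maxLevel` 1 and
#' each rule as a `qual:transition` whose level-1 function term encodes the
#' rule as a MathML `and`/`or`/`not` tree over `eq(node, 1)` leaves.  Input
#' nodes get no transition.
#'
#' @param net a [regulatory_network].
#' @param path output file path.
#' @export
write_sbml_qual <- function(net, path) {
  assert_network(net)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns, "xmlns:qual" = qual_ns,
    level = "3", version = "1", "qual:required" = "true")
  model <- xml2::xml_add_child(doc, "model", id = "network")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "true")
  qs <- xml2::xml_add_child(model, "qual:listOfQualitativeSpecies")
  for (nm in net$nodes)
    xml2::xml_add_child(qs, "qual:qualitativeSpecies",
                        "qual:id" = nm, "qual:compartment" = "cell",
                        "qual:constant" = "false", "qual:maxLevel" = "1")
  trs <- xml2::xml_add_child(model, "qual:listOfTransitions")
  for (nm in names(net$rules)) {
    tr <- xml2::xml_add_child(trs, "qual:transition",
                              "qual:id" = paste0("tr_", nm))
    regs <- unique(rule_literals(net$rules[[nm]])$node)
    ins <- xml2::xml_add_child(tr, "qual:listOfInputs")
    for (rg in regs)
      xml2::xml_add_child(ins, "qual:input",
                          "qual:qualitativeSpecies" = rg,
                          "qual:transitionEffect" = "none")
    outs <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(outs, "qual:output",
                        "qual:qualitativeSpecies" = nm,
                        "qual:transitionEffect" = "assignmentLevel")
    fts <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    xml2::xml_add_child(fts, "qual:defaultTerm", "qual:resultLevel" = "0")
    ft <- xml2::xml_add_child(fts, "qual:functionTerm",
                              "qual:resultLevel" = "1")
    math <- xml2::xml_add_child(ft, "math", xmlns = mathml_ns)
    add_mathml(math, net$rules[[nm]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# rule AST -> MathML under `parent`
add_mathml <- function(parent, expr) {
  if (is.symbol(expr)) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, "eq")
    xml2::xml_add_child(ap, "ci", as.character(expr))
    xml2::xml_add_child(ap, "cn", "1", type = "integer")
    return(invisible(parent))
  }
  if (is.numeric(expr) || is.logical(expr)) {
    xml2::xml_add_child(parent, if (as.numeric(expr) == 1) "true" else "false")
    return(invisible(parent))
  }
  op <- as.character(expr[[1]])
  if (op == "(") return(add_mathml(parent, expr[[2]]))
  ap <- xml2::xml_add_child(parent, "apply")
  tag <- switch(op, "&" = , "&&" = "and", "|" = , "||" = "or", "!" = "not",
                stop("cannot encode operator '", op, "'", call. = FALSE))
  xml2::xml_add_child(ap, tag)
  for (i in seq_along(expr)[-1]) add_mathml(ap, expr[[i]])
  invisible(parent)
}

#' Import a network from SBML-qual (subset)
#'
#' Reads the subset written by [write_sbml_qual()]: binary qualitative
#' species and transitions whose level-1 function term is an and/or/not
#' MathML tree over `eq(node, 1)` leaves.  Species without a transition
#' become input nodes.
#'
#' @param path SBML-qual file path.
#' @return a [regulatory_network].
#' @export
read_sbml_qual <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  # namespace-agnostic navigation (files may use any qual prefix)
  ln <- function(name) paste0("*[local-name()='", name, "']")
  species <- xml2::xml_find_all(
    doc, paste0(".//", ln("listOfQualitativeSpecies"), "/",
                ln("qualitativeSpecies")))
  ids <- vapply(species, function(s) qattr(s, "id"), "")
  if (length(ids) == 0L)
    stop("no qualitative species found in ", path, call. = FALSE)
  rules <- list()
  for (tr in xml2::xml_find_all(doc, paste0(".//", ln("transition")))) {
    out <- xml2::xml_find_first(tr, paste0(".//", ln("output")))
    tgt <- qattr(out, "qualitativeSpecies")
    ft <- xml2::xml_find_first(tr, paste0(".//", ln("functionTerm")))
    if (inherits(ft, "xml_missing") || is.na(tgt)) next
    math <- xml2::xml_find_first(ft, paste0("./", ln("math"), "/*"))
    rules[[tgt]] <- mathml_to_rule(math)
  }
  inputs <- setdiff(ids, names(rules))
  regulatory_network(rules, inputs = inputs)
}

# attribute access tolerant of qual: prefixes surviving xml_ns_strip
qattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("qual:", name))
  v
}

mathml_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "true") return(1)
  if (nm == "false") return(0)
  if (nm != "apply")
    stop("unsupported MathML element '", nm, "'", call. = FALSE)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  if (op == "eq") {
    ci <- args[[which(vapply(args, xml2::xml_name, "") == "ci")]]
    return(as.symbol(trimws(xml2::xml_text(ci))))
  }
  if (op == "not") return(call("!", mathml_to_rule(args[[1]])))
  if (op %in% c("and", "or")) {
    rop <- if (op == "and") "&" else "|"
    sub <- lapply(args, mathml_to_rule)
    return(Reduce(function(a, b) call(rop, a, b), sub))
  }
  stop("unsupported MathML operator '", op, "'", call. = FALSE)
}

# ---------------------------------------------------------------------------
# graph exports

#' Convert a network's interaction list to an igraph object
#'
#' Vertices are nodes (with their category as attribute); edges carry the
#' interaction `sign`.
#'
#' @param net a [regulatory_network].
#' @return an igraph directed graph.
#' @export
as_igraph <- function(net) {
  assert_network(net)
  edges <- extract_interactions(net)
  igraph::graph_from_data_frame(
    edges,
    vertices = data.frame(name = net$nodes,
                          category = net$categories[net$nodes]))
}

#' Export the signed interaction network
#'
#' `write_sif()` writes one `source <sign> target` line per interaction
#' (signs `+`/`-`); `write_graphml()` writes GraphML with a `sign` edge
#' attribute via igraph.
#'
#' @param net a [regulatory_network].
#' @param path output path.
#' @export
write_sif <- function(net, path) {
  edges <- extract_interactions(net)
  writeLines(paste(edges$source,
                   ifelse(edges$sign == "positive", "+", "-"),
                   edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a fate map to DOT
#'
#' Edge labels use the symbols `-`, `+` and `int` for perturbation levels
#' 0, 1 and intermediate.
#'
#' @param fmap a `fate_map`.
#' @param path output path.
#' @export
write_fate_map_dot <- function(fmap, path) {
  sym <- function(lv) if (lv == 0) "-" else if (lv == 1) "+" else "int"
  lines <- c("digraph fatemap {",
             sprintf('  "%s";', fmap$vertices$label))
  if (nrow(fmap$edges) > 0L)
    lines <- c(lines, vapply(seq_len(nrow(fmap$edges)), function(r)
      sprintf('  "%s" -> "%s" [label="%s%s"];',
              fmap$vertices$label[fmap$edges$source[r]],
              fmap$vertices$label[fmap$edges$target[r]],
              fmap$edges$node[r], sym(fmap$edges$level[r])), ""))
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' @rdname write_fate_map_dot
#' @export
fate_map_igraph <- function(fmap) {
  igraph::graph_from_data_frame(
    data.frame(from = fmap$vertices$label[fmap$edges$source],
               to = fmap$vertices$label[fmap$edges$target],
               node = fmap$edges$node,
               level = fmap$edges$level),
    vertices = fmap$vertices$label)
}

# ---------------------------------------------------------------------------
# result tables

#' Write attractor tables to CSV or JSON
#'
#' Discrete sets export the tidy frame of [as.data.frame.attractor_set()];
#' continuous sets export a node x attractor matrix of levels plus support
#' counts, residuals and discovery mode.
#'
#' @param x an `attractor_set` or `continuous_attractor_set`.
#' @param path output path; `.json` selects JSON, anything else CSV.
#' @export
write_attractor_table <- function(x, path) {
  if (inherits(x, "attractor_set")) {
    df <- as.data.frame(x)
  } else if (inherits(x, "continuous_attractor_set")) {
    nodes <- attr(x, "nodes")
    rows <- lapply(seq_along(x), function(i) {
      a <- x[[i]]
      cbind(data.frame(attractor = i,
                       support = if (is.null(a$support_count)) NA
                                 else a$support_count,
                       residual = a$residual,
                       discovered_by = a$discovered_by),
            as.data.frame(as.list(a$levels)))
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else stop("unsupported object", call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  else
    utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
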