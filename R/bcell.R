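#' The six core master regulators of terminal B-cell differentiation
#'
#' The stationary pattern over these nodes defines the cell-type label of an
#' attractor, reported in the fixed order Bach2, Bcl6, Blimp1, Irf4, Pax5,
#' XBP1.
#' @export
bcell_core_nodes <- c("Bach2", "Bcl6", "Blimp1", "Irf4", "Pax5", "XBP1")

#' Load the packaged B-cell terminal differentiation network
#'
#' Returns the curated 22-node logical model of terminal B-cell
#' differentiation: six core master regulators (Bach2, Bcl6, Blimp1, Irf4,
#' Pax5, XBP1), five extracellular input signals (Ag, CD40L, IL2, IL4, IL21)
#' and the signal-transduction cascades connecting them
#' (Ag/BCR/ERK, CD40L/CD40/NFkB, IL2/IL2R/STAT5, IL4/IL4R/STAT6,
#' IL21/IL21R/STAT3).  Seventeen nodes carry a logic rule; the five inputs
#' are regulator-free and decay to 0 unless clamped.  The rules encode 39
#' signed regulatory interactions, including four predicted ones:
#' Pax5 activates Bcl6, Irf4 inhibits Pax5, and Bcl6 and Pax5 each sustain
#' themselves.
#'
#' Node names are ASCII identifiers: `IL2`, `IL4`, `IL21` (and their
#' receptors) stand for IL-2, IL-4 and IL-21, and `NFkB` for NF-kappaB.
#'
#' @return a [regulatory_network] with 22 nodes.
#' @examples
#' net <- load_bcell_network()
#' net$rules$XBP1  # Blimp1 & !Pax5
#' @export
load_bcell_network <- function() {
  rules <- list(
    AID    = "(STAT6 | (NFkB & Pax5)) & !Blimp1",
    Bach2  = "Pax5 & !Blimp1",
    Bcl6   = "(STAT5 | STAT6 | (Pax5 & Bcl6)) & !(Blimp1 | Irf4 | ERK)",
    BCR    = "Ag",
    Blimp1 = "(ERK | STAT3) | (Irf4 & !(Pax5 | Bcl6 | Bach2))",
    CD40   = "CD40L",
    ERK    = "BCR",
    IL2R   = "IL2",
    IL4R   = "IL4",
    IL21R  = "IL21",
    Irf4   = "(NFkB | Irf4) | (Blimp1 & !Bcl6)",
    NFkB   = "CD40",
    Pax5   = "(Pax5 | !Irf4) & !(Blimp1 | ERK)",
    STAT3  = "IL21R",
    STAT5  = "IL2R",
    STAT6  = "IL4R",
    XBP1   = "Blimp1 & !Pax5")
  inputs <- c("Ag", "CD40L", "IL2", "IL4", "IL21")
  categories <- c(
    stats::setNames(rep("core", length(bcell_core_nodes)), bcell_core_nodes),
    stats::setNames(rep("environment", length(inputs)), inputs))
  regulatory_network(rules, inputs = inputs, categories = categories)
}

#' Core-module activation pattern of a state
#'
#' Projects a full state onto the six core master regulators, in the fixed
#' reporting order `Bach2, Bcl6, Blimp1, Irf4, Pax5, XBP1`.
#'
#' @param state a named state vector (Boolean or continuous).
#' @return named numeric vector of length 6.
#' @export
core_pattern <- function(state) {
  missing <- setdiff(bcell_core_nodes, names(state))
  if (length(missing) > 0L)
    stop("state lacks core node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- as.numeric(state[bcell_core_nodes])
  names(out) <- bcell_core_nodes
  out
}

#' Cell-type signatures over the core module
#'
#' The four canonical activation patterns over
#' `[Bach2, Bcl6, Blimp1, Irf4, Pax5, XBP1]` that define the Naive, GC
#' (germinal center), Mem (memory) and PC (plasma cell) labels:
#' Naive `[1,0,0,0,1,0]`, GC `[1,1,0,0,1,0]`, Mem `[1,0,0,1,1,0]`,
#' PC `[0,0,1,1,0,1]`.  The four signatures are mutually exclusive.
#'
#' @return a 4 x 6 numeric matrix with row names Naive/GC/Mem/PC and column
#'   names the core nodes.
#' @export
cell_type_signatures <- function() {
  m <- rbind(
    Naive = c(1, 0, 0, 0, 1, 0),
    GC    = c(1, 1, 0, 0, 1, 0),
    Mem   = c(1, 0, 0, 1, 1, 0),
    PC    = c(0, 0, 1, 1, 0, 1))
  colnames(m) <- bcell_core_nodes
  m
}
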