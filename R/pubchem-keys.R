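# PubChem-layout 881-bit substructure-key fingerprint definitions.
#
# The official CACTVS key table is not redistributable here, so the
# package ships its own layout-faithful table: the overall section
# structure of the 881-bit fingerprint is preserved (hierarchic element
# counts first, the ring-count block occupying exactly bits 115-262,
# then element-pair and SMARTS substructure keys), the first 49
# element-count thresholds follow the well-known official values, and
# all remaining high bits are reserved (never set). Individual bit
# semantics beyond that are the package's own; downstream code depends
# only on the length contract (881), the ring-block range and the
# substructure/occurrence retro-mapping semantics.

.pubchemState <- new.env(parent = emptyenv())

# bits 0-48: official hierarchic element-count thresholds
.pcElementCounts <- function() {
  tab <- list(
    H = c(4, 8, 16, 32), Li = c(1, 2), B = c(1, 2, 4),
    C = c(2, 4, 8, 16, 32), N = c(1, 2, 4, 8), O = c(1, 2, 4, 8, 16),
    F = c(1, 2, 4), Na = c(1, 2), Si = c(1, 2), P = c(1, 2, 4),
    S = c(1, 2, 4, 8), Cl = c(1, 2, 4, 8), K = c(1, 2), Br = c(1, 2, 4),
    I = c(1, 2, 4))
  el <- rep(names(tab), lengths(tab))
  thr <- unlist(tab, use.names = FALSE)
  # bits 49-114: single-presence keys for 66 further elements
  rare <- c("Be", "Mg", "Al", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
            "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Kr", "Rb",
            "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag",
            "Cd", "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "Lu", "Hf",
            "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb",
            "Bi", "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb",
            "Dy", "Ho", "Er", "Tm", "Yb", "U")
  data.frame(element = c(el, rare), threshold = c(thr, rep(1L, length(rare))),
             stringsAsFactors = FALSE)
}

# bits 115-262: ring-count block, systematic (size x class x threshold)
.pcRingBlock <- function() {
  classes <- c("carbo_satarom", "n_satarom", "het_satarom",
               "carbo_unsat", "n_unsat", "het_unsat")
  rows <- list()
  for (size in 3:10) {
    thrs <- if (size %in% c(5L, 6L)) 1:5 else 1:2
    for (cl in classes) {
      for (t in thrs) {
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, rclass = cl, threshold = t,
          cluster = sprintf("ring_s%d_%s", size, cl),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (size in 3:10)
    rows[[length(rows) + 1L]] <- data.frame(
      size = size, rclass = "any", threshold = 1L,
      cluster = sprintf("ring_s%d_any", size), stringsAsFactors = FALSE)
  for (t in 1:4)
    rows[[length(rows) + 1L]] <- data.frame(
      size = NA_integer_, rclass = "aromatic", threshold = t,
      cluster = "ring_aromatic", stringsAsFactors = FALSE)
  for (t in 1:4)
    rows[[length(rows) + 1L]] <- data.frame(
      size = NA_integer_, rclass = "hetero_aromatic", threshold = t,
      cluster = "ring_heteroaromatic", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# bits 263-326: element-pair bond keys ("X~Y", any bond order)
.pcPairs <- function() {
  c("Li-H", "Li-Li", "B-H", "B-B", "B-C", "B-N", "B-O", "B-F", "B-Si",
    "B-P", "B-S", "B-Cl", "B-Br", "C-H", "C-C", "C-N", "C-O", "C-F",
    "C-Na", "C-Mg", "C-Al", "C-Si", "C-P", "C-S", "C-Cl", "C-As",
    "C-Se", "C-Br", "C-I", "N-H", "N-N", "N-O", "N-F", "N-Si", "N-P",
    "N-S", "N-Cl", "N-Br", "O-H", "O-O", "O-Mg", "O-Na", "O-Al",
    "O-Si", "O-P", "O-K", "O-S", "O-Cl", "F-P", "F-S", "Si-H",
    "Si-Si", "Si-Cl", "P-H", "P-P", "P-S", "As-H", "As-As", "S-H",
    "S-S", "S-Cl", "S-Br", "Se-H", "Se-Se")
}

.pcPairSmarts <- function(pair) {
  z <- c(H = 1, Li = 3, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
         Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
         As = 33, Se = 34, Br = 35, I = 53)
  els <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (els[2] == "H") return(sprintf("[#%d;!H0]", z[[els[1]]]))
  sprintf("[#%d]~[#%d]", z[[els[1]]], z[[els[2]]])
}

# bits 327+: functional-group / atom-environment SMARTS keys
.pcSmartsKeys <- function() {
  c(
    "[CX3]=[OX1]", "[CX3](=O)[OX2H1]", "[CX3](=O)[OX2][#6]",
    "[CX3](=O)[NX3]", "[CX3H1]=[OX1]", "[#6][CX3](=O)[#6]",
    "[OD2]([#6])[#6]", "[OX2H]", "c[OX2H]",
    "[NX3;H2;!$(NC=O)]", "[NX3;H1]([#6])[#6]", "[NX3]([#6])([#6])[#6]",
    "c[NX3]", "[O-][N+]=O", "c[N+](=O)[O-]", "[CX4][N+](=O)[O-]",
    "[NX2]=[OX1]", "N=N", "C#N", "N=C=O", "N=C=S",
    "[SX2H]", "[SX2]([#6])[#6]", "[SX2][SX2]",
    "[#16X3]=[OX1]", "[#16X4](=[OX1])=[OX1]", "[SX4](=O)(=O)[NX3]",
    "S(=O)(=O)[OX2]",
    "[PX4]=[OX1]", "[PX4]=[SX1]", "[PX4](=[OX1])([OX2])[OX2]",
    "[PX4](=[SX1])([OX2])[OX2]", "[OX2][PX4]",
    "cF", "cCl", "cBr", "cI",
    "[CX4]F", "[CX4]Cl", "[CX4]Br", "[CX4]I", "[CX4](F)(F)F",
    "c1ccccc1", "c1ccncc1", "c1cncnc1", "c1cc[nH]c1", "c1ccoc1",
    "c1ccsc1", "c1cnc[nH]1", "c1ccc2ccccc2c1",
    "[CX3]=[CX3]", "C#C", "[CX3]=[CX3][CX3](=O)[OX2]",
    "NC(=N)N", "[NX3][CX3](=O)[NX3]", "[NX3][CX3](=O)[OX2]",
    "C1OC1", "C1NC1",
    "[#6](~[#6])~[#6]", "[#6](~[#6])(~[#6])~[#6]",
    "[#6](~[#6])(~[#6])(~[#6])~[#6]",
    "[#6](~[#6])~[#7]", "[#6](~[#6])~[#8]", "[#6](~[#7])~[#8]",
    "[#6](~[#8])~[#8]", "[#7](~[#6])~[#6]", "[#8](~[#6])~[#6]",
    "[#6](~[#6])~[#16]", "[#7](~[#6])~[#8]",
    "[#6]~[#6]~[#6]~[#6]", "[#6]~[#6]~[#7]", "[#6]~[#6]~[#8]",
    "[#8]~[#6]~[#8]", "[#7]~[#6]~[#7]", "[#16]~[#6]~[#7]",
    "c-[CX4]", "c-[NX3]", "c-[OX2]", "c-[#16]",
    "[CH3]", "[CH2]", "[CH1]", "[NH2]", "[NX3H1]", "[OX2H1]",
    "[cH0]", "[R2]", "[R1;CX4]", "[R1;c]",
    "O=C-N-C=O", "O=C-C=C", "N-C-C-O", "S-C-C-O", "Cl-C-C-Cl",
    "[#7;R]", "[#8;R]", "[#16;R]"
  )
}

#' The 881-bit PubChem-layout key table
#'
#' Builds (and caches) the per-bit definition table of the package's
#' 881-bit substructure-key fingerprint: element-count keys (bits
#' 0--114), the ring-count block (bits 115--262), element-pair bond keys
#' (bits 263--326), SMARTS functional-group/environment keys from bit
#' 327, and reserved (never-set) bits filling the remainder to 881.
#'
#' @return a `data.frame` with columns `bit` (0-based), `kind`
#'   (`element_count`, `ring`, `smarts`, `reserved`), `element`,
#'   `threshold`, `size`, `rclass`, `smarts`, `cluster`.
#' @export
pubchemKeyTable <- function() {
  if (!is.null(.pubchemState$table)) return(.pubchemState$table)
  ec <- .pcElementCounts()
  ring <- .pcRingBlock()
  pairs <- .pcPairs()
  fg <- .pcSmartsKeys()
  n <- 881L
  tab <- data.frame(bit = 0:(n - 1L), kind = "reserved",
                    element = NA_character_, threshold = NA_integer_,
                    size = NA_integer_, rclass = NA_character_,
                    smarts = NA_character_, cluster = NA_character_,
                    stringsAsFactors = FALSE)
  stopifnot(nrow(ec) == 115L, nrow(ring) == 148L)
  i <- seq_len(nrow(ec))
  tab$kind[i] <- "element_count"
  tab$element[i] <- ec$element
  tab$threshold[i] <- ec$threshold
  i <- 115L + seq_len(nrow(ring))
  tab$kind[i] <- "ring"
  tab$size[i] <- ring$size
  tab$rclass[i] <- ring$rclass
  tab$threshold[i] <- ring$threshold
  tab$cluster[i] <- ring$cluster
  i <- 263L + seq_along(pairs)
  tab$kind[i] <- "smarts"
  tab$smarts[i] <- vapply(pairs, .pcPairSmarts, character(1))
  tab$threshold[i] <- 1L
  i <- 327L + seq_along(fg)
  tab$kind[i] <- "smarts"
  tab$smarts[i] <- fg
  tab$threshold[i] <- 1L
  stopifnot(max(i) <= n)
  .pubchemState$table <- tab
  tab
}

#' Ring-bit clusters of the PubChem-layout fingerprint
#'
#' Bits 115--262 encode ring-system presence at increasing occurrence
#' thresholds; bits describing the same ring class and differing only in
#' the count threshold are redundant for atom attribution. This returns
#' the disjoint cluster assignment used by [clusterRingBits()].
#'
#' @return named list: cluster id -> integer vector of 0-based bit
#'   indices, covering every bit in 115--262 exactly once.
#' @export
ringBitClusters <- function() {
  tab <- pubchemKeyTable()
  rb <- tab[tab$kind == "ring", ]
  split(rb$bit, rb$cluster)
}

# Serializable key list for the Python bridge.
pubchemKeysPayload <- function() {
  if (!is.null(.pubchemState$payload)) return(.pubchemState$payload)
  tab <- pubchemKeyTable()
  keys <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    switch(r$kind,
      element_count = list(bit = r$bit, kind = "element_count",
                           element = r$element, threshold = r$threshold),
      ring = {
        k <- list(bit = r$bit, kind = "ring", rclass = r$rclass,
                  threshold = r$threshold)
        if (!is.na(r$size)) k$size <- r$size
        k
      },
      smarts = list(bit = r$bit, kind = "smarts", smarts = r$smarts,
                    threshold = r$threshold),
      NULL)
  })
  .pubchemState$payload <- Filter(Negate(is.null), keys)
  .pubchemState$payload
}
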