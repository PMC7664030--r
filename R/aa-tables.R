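#' Amino-acid physicochemical property table
#'
#' Per-residue properties used to quantify the physicochemical change of a
#' kinase point substitution: net side-chain charge at physiological pH
#' (unit charges; His carries +0.5), a binary polarity class (polar = 1),
#' Kyte-Doolittle hydrophobicity, theoretical maximum accessible surface
#' area (A^2, Tien et al. 2013), residue volume (A^3, Zamyatnin 1972), and a
#' per-residue transfer free energy (kcal/mol, Fauchere-Pliska octanol
#' scale) serving as the energy term. Any column can be swapped for an
#' alternative scale via `override`; the substitution-score column always
#' comes from BLOSUM62 (see [blosum62()]).
#'
#' @param override Optional data frame with column `residue` plus any of
#'   `charge`, `polarity`, `hydrophobicity`, `asa`, `volume`, `energy`;
#'   matching cells replace the packaged values.
#'
#' @return A data frame with one row per canonical residue (rownames =
#'   one-letter codes) and columns `residue`, `charge`, `polarity`,
#'   `hydrophobicity`, `asa`, `volume`, `energy`.
#' @examples
#' props <- aa_properties()
#' props["R", "charge"] - props["L", "charge"]  # +1: the L858R charge gain
#' @export
aa_properties <- function(override = NULL) {
  tab <- data.frame(
    residue = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0.5, 0,
               0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    polarity = c(0, 1, 1, 1, 1, 1, 1, 0, 1, 0,
                 0, 1, 0, 0, 0, 1, 1, 0, 1, 0),
    hydrophobicity = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2,
                       4.5, 3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9,
                       -1.3, 4.2),
    asa = c(129, 274, 195, 193, 167, 225, 223, 104, 224, 197,
            201, 236, 224, 240, 159, 155, 172, 285, 263, 174),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
               166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
               193.6, 140.0),
    energy = c(0.31, -1.01, -0.60, -0.77, 1.54, -0.22, -0.64, 0.00, 0.13,
               1.80, 1.70, -0.99, 1.23, 1.79, 0.72, -0.04, 0.26, 2.25,
               0.96, 1.22),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$residue
  if (!is.null(override)) {
    if (!"residue" %in% names(override))
      stop("override must have a 'residue' column", call. = FALSE)
    cols <- intersect(names(override), setdiff(names(tab), "residue"))
    for (cl in cols) {
      idx <- match(override$residue, tab$residue)
      if (anyNA(idx)) stop("override contains a non-canonical residue")
      tab[[cl]][idx] <- override[[cl]]
    }
  }
  tab
}

#' BLOSUM62 substitution matrix
#'
#' The 20x20 canonical-residue block of the BLOSUM62 amino-acid substitution
#' matrix, taken from Biostrings and cached after first use.
#'
#' @return A symmetric 20x20 integer matrix indexed by one-letter residue
#'   codes.
#' @examples
#' blosum62()["L", "R"]  # -2
#' @export
blosum62 <- function() {
  if (is.null(.qsmart_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa <- aa_properties()$residue
    .qsmart_env$blosum62 <- e$BLOSUM62[aa, aa]
  }
  .qsmart_env$blosum62
}
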