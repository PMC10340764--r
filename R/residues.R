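# Residue-level metadata consumed by every other module.

#' Canonical amino-acid metadata table
#'
#' Returns the per-residue metadata that underpins mass calculation, motif
#' flagging, nutritional class sums and taste-activity values: one row per
#' canonical amino acid with its one- and three-letter codes, monoisotopic and
#' average residue masses (Da), class membership flags and, where defined, a
#' taste threshold (mg/100 g).
#'
#' Class membership follows the food-science conventions used throughout the
#' package:
#' \itemize{
#'   \item \code{hydrophobic}: Ala, Val, Ile, Leu, Phe, Met, Pro.
#'   \item \code{essential}: Thr, Val, Met, Ile, Leu, Phe, Lys, Trp (the
#'     grouping used for cereal-protein EAA totals; His is counted
#'     non-essential here even though the WHO/FAO adult scoring pattern
#'     includes it).
#'   \item \code{flavour_class}: \code{"fresh"} (umami; Glu, Asp),
#'     \code{"bitter"} (Val, Met, Ile, Leu, Phe, His, Arg), \code{"sweet"}
#'     (Thr, Ser, Gly, Ala), otherwise \code{"none"}.
#'   \item \code{medicinal}: Met, Leu, Phe, Lys, Asp, Tyr, Glu, Ala, Arg.
#' }
#'
#' Taste thresholds are defined for the fourteen flavour-presenting residues
#' (Glu 30, Asp 100, Arg 10, His 20, Met 30, Ile 90, Leu 380, Phe 150, Trp 90,
#' Val 150, Ala 60, Gly 110, Ser 150, Thr 260 mg/100 g); the remainder are
#' \code{NA}.
#'
#' @return A \code{data.frame} with 20 rows and columns \code{one_letter},
#'   \code{three_letter}, \code{monoisotopic_mass}, \code{average_mass},
#'   \code{hydrophobic}, \code{essential}, \code{flavour_class},
#'   \code{medicinal}, \code{taste_threshold}.
#' @examples
#' rt <- residue_table()
#' rt[rt$one_letter == "L", ]
#' @export
residue_table <- function() {
  tab <- data.frame(
    one_letter = c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                   "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
    three_letter = c("Gly", "Ala", "Ser", "Pro", "Val", "Thr", "Cys", "Leu",
                     "Ile", "Asn", "Asp", "Gln", "Lys", "Glu", "Met", "His",
                     "Phe", "Arg", "Tyr", "Trp"),
    monoisotopic_mass = c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841,
                          101.04768, 103.00919, 113.08406, 113.08406,
                          114.04293, 115.02694, 128.05858, 128.09496,
                          129.04259, 131.04049, 137.05891, 147.06841,
                          156.10111, 163.06333, 186.07931),
    average_mass = c(57.0519, 71.0788, 87.0782, 97.1167, 99.1326, 101.1051,
                     103.1388, 113.1594, 113.1594, 114.1038, 115.0886,
                     128.1307, 128.1741, 129.1155, 131.1926, 137.1411,
                     147.1766, 156.1875, 163.1760, 186.2132),
    stringsAsFactors = FALSE
  )
  tab$hydrophobic <- tab$one_letter %in% c("A", "V", "I", "L", "F", "M", "P")
  tab$essential <- tab$one_letter %in% c("T", "V", "M", "I", "L", "F", "K", "W")
  tab$flavour_class <- "none"
  tab$flavour_class[tab$one_letter %in% c("E", "D")] <- "fresh"
  tab$flavour_class[tab$one_letter %in% c("V", "M", "I", "L", "F", "H", "R")] <- "bitter"
  tab$flavour_class[tab$one_letter %in% c("T", "S", "G", "A")] <- "sweet"
  tab$medicinal <- tab$one_letter %in%
    c("M", "L", "F", "K", "D", "Y", "E", "A", "R")
  thr <- c(E = 30, D = 100, R = 10, H = 20, M = 30, I = 90, L = 380,
           F = 150, W = 90, V = 150, A = 60, G = 110, S = 150, T = 260)
  tab$taste_threshold <- unname(thr[tab$one_letter])
  tab
}

# Mass of one water molecule, added once per peptide chain.
WATER_MONO <- 18.010565
WATER_AVG  <- 18.01528

#' Validate a peptide/protein sequence string
#'
#' Uppercases the sequence and checks that every character is one of the 20
#' canonical one-letter amino-acid codes. Non-canonical codes (B, J, O, U, X,
#' Z), digits, gaps and stops are rejected, with the offending positions named.
#'
#' @param sequence Character scalar.
#' @param what Label used in error messages.
#' @return The validated, uppercased sequence.
#' @export
validate_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string")
  seq <- toupper(sequence)
  if (nchar(seq) == 0L)
    stop(what, " must be non-empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% residue_table()$one_letter)
  if (length(bad))
    stop(what, " contains invalid residue character(s) ",
         paste0("'", chars[bad], "'", collapse = ", "),
         " at position(s) ", paste(bad, collapse = ", "))
  seq
}
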