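# Amino-acid-based nutritional and flavour quality indices: AAS, the three
# PER regressions, class sums/ratios and taste-activity values.

# Map three-letter codes to one-letter, tolerating either on input.
normalise_residue_names <- function(nms) {
  rt <- residue_table()
  three <- stats::setNames(rt$three_letter, rt$one_letter)
  out <- ifelse(nms %in% rt$three_letter, nms,
                ifelse(toupper(nms) %in% rt$one_letter,
                       unname(three[toupper(nms)]), NA_character_))
  if (anyNA(out))
    stop("unknown residue name(s): ", paste(nms[is.na(out)], collapse = ", "))
  out
}

#' Construct an amino-acid composition profile
#'
#' @param content Named numeric vector of residue contents in g/100 g sample;
#'   names may be one- or three-letter codes. Residues absent from the vector
#'   are treated as 0 g/100 g with a warning (Trp is commonly not detected
#'   after acid hydrolysis and may legitimately be 0).
#' @param sample_id Sample label.
#' @return An \code{aa_profile} object: list with \code{sample_id} and
#'   \code{content}, a full 20-residue named vector (three-letter names).
#' @examples
#' amino_acid_profile(c(Leu = 17.62, Pro = 8.34), "toy")
#' @export
amino_acid_profile <- function(content, sample_id = "sample") {
  stopifnot(is.numeric(content), length(content) >= 1L,
            !is.null(names(content)))
  if (any(content < 0)) stop("amino-acid contents must be non-negative")
  nms <- normalise_residue_names(names(content))
  if (anyDuplicated(nms)) stop("duplicate residue entries in profile")
  rt <- residue_table()
  full <- stats::setNames(numeric(20), rt$three_letter)
  full[nms] <- unname(content)
  missing <- setdiff(rt$three_letter, nms)
  if (length(missing))
    warning("residue(s) absent from profile treated as 0 g/100 g: ",
            paste(missing, collapse = ", "))
  structure(list(sample_id = sample_id, content = full), class = "aa_profile")
}

#' Read amino-acid profiles from a CSV
#'
#' Expects a \code{residue} column (one- or three-letter codes) and one
#' numeric column per sample, contents in g/100 g.
#'
#' @param path CSV path.
#' @return Named list of [amino_acid_profile()] objects, one per sample column.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"residue" %in% names(tab)) stop("profile CSV must have a 'residue' column")
  samples <- setdiff(names(tab), "residue")
  stats::setNames(lapply(samples, function(s) {
    suppressWarnings(amino_acid_profile(
      stats::setNames(as.numeric(tab[[s]]), tab$residue), sample_id = s))
  }), samples)
}

#' WHO/FAO adult amino-acid scoring pattern
#'
#' The adult reference pattern in mg of amino acid per g of protein, with the
#' usual pairing of the sulfur (Met+Cys) and aromatic (Phe+Tyr) amino acids.
#' Overridable: pass any named vector of the same shape to [aas()].
#'
#' @return Named numeric vector (mg/g protein).
#' @export
fao_who_adult_pattern <- function() {
  c(His = 15, Ile = 30, Leu = 59, Lys = 45, `Met+Cys` = 22,
    `Phe+Tyr` = 38, Thr = 23, Trp = 6, Val = 39)
}

# Content of a residue-or-pair key ("Leu", "Phe+Tyr") from a full profile
# vector, in the profile's own units.
pattern_content <- function(content, key) {
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  sum(content[normalise_residue_names(trimws(parts))])
}

#' Amino acid score against a reference pattern
#'
#' \code{AAS = 100 * content / reference} per scored residue (or residue
#' pair). In the default normalised mode the profile is first converted to mg
#' of amino acid per g of total amino acids so that its units match a
#' reference pattern expressed per g protein; \code{normalise = FALSE}
#' divides the raw contents directly (unit-agnostic ratio mode).
#'
#' Residues whose measured content is zero (e.g. Trp not detected after acid
#' hydrolysis) are scored \code{NA} and set aside from the limiting-residue
#' ranking rather than reported as the limiting amino acid.
#'
#' @param profile An [amino_acid_profile()].
#' @param reference Named vector, mg/g protein, as [fao_who_adult_pattern()].
#' @param normalise Normalise profile to mg/g of total amino acids first
#'   (default \code{TRUE}).
#' @return List with \code{scores} (named numeric) and \code{limiting}
#'   (residue keys ordered by ascending score).
#' @export
aas <- function(profile, reference = fao_who_adult_pattern(),
                normalise = TRUE) {
  stopifnot(inherits(profile, "aa_profile"), is.numeric(reference),
            !is.null(names(reference)))
  if (any(reference <= 0)) stop("reference pattern entries must be positive")
  content <- profile$content
  if (normalise) {
    taa <- sum(content)
    if (taa <= 0) stop("profile has zero total amino-acid content")
    content <- content / taa * 1000  # g/100g -> mg per g of TAA
  }
  scores <- vapply(names(reference), function(k) {
    x <- pattern_content(content, k)
    if (x == 0) NA_real_ else 100 * x / reference[[k]]
  }, 0)
  ranked <- scores[!is.na(scores)]
  list(scores = scores, limiting = names(sort(ranked)))
}

#' Protein efficiency ratio regressions
#'
#' Three literature regressions on amino-acid contents (g/100 g):
#' \deqn{PER_1 = -0.684 + 0.456\,Leu - 0.047\,Pro}
#' \deqn{PER_2 = -0.468 + 0.454\,Leu - 0.105\,Tyr}
#' \deqn{PER_3 = -1.816 + 0.435\,Met + 0.78\,Leu + 0.211\,His - 0.944\,Tyr}
#' A value above 2 indicates good protein quality.
#'
#' @param profile An [amino_acid_profile()].
#' @return Named numeric vector \code{c(per1, per2, per3)}, full precision.
#' @examples
#' p <- suppressWarnings(amino_acid_profile(
#'   c(Leu = 17.62, Pro = 8.34, Tyr = 4.81, Met = 1.13, His = 1.12)))
#' round(per(p), 2)  # 6.96 7.03 8.11
#' @export
per <- function(profile) {
  stopifnot(inherits(profile, "aa_profile"))
  x <- profile$content
  c(per1 = -0.684 + 0.456 * x[["Leu"]] - 0.047 * x[["Pro"]],
    per2 = -0.468 + 0.454 * x[["Leu"]] - 0.105 * x[["Tyr"]],
    per3 = -1.816 + 0.435 * x[["Met"]] + 0.78 * x[["Leu"]] +
      0.211 * x[["His"]] - 0.944 * x[["Tyr"]])
}

#' Amino-acid class sums and ratios
#'
#' Sums the profile over the residue classes of [residue_table()]:
#' total (TAA), essential (EAA), non-essential (NEAA), hydrophobic (HAA),
#' fresh/umami (F = Glu + Asp), bitter (B), sweet (S = Thr + Ser + Gly + Ala)
#' and medicinal (D) amino acids, plus the percentage ratios EAA/TAA,
#' EAA/NEAA, F/T, B/T, S/T and D/T.
#'
#' @param profile An [amino_acid_profile()].
#' @return Named numeric vector of sums (g/100 g) and ratios (percent).
#' @export
class_sums <- function(profile) {
  stopifnot(inherits(profile, "aa_profile"))
  rt <- residue_table()
  x <- profile$content[rt$three_letter]
  taa <- sum(x)
  eaa <- sum(x[rt$essential])
  neaa <- taa - eaa
  haa <- sum(x[rt$hydrophobic])
  f <- sum(x[rt$flavour_class == "fresh"])
  b <- sum(x[rt$flavour_class == "bitter"])
  s <- sum(x[rt$flavour_class == "sweet"])
  d <- sum(x[rt$medicinal])
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(taa = taa, eaa = eaa, neaa = neaa, haa = haa, f = f, b = b, s = s, d = d,
    eaa_taa = pct(eaa, taa), eaa_neaa = pct(eaa, neaa), f_t = pct(f, taa),
    b_t = pct(b, taa), s_t = pct(s, taa), d_t = pct(d, taa))
}

#' Taste-activity values and class totals
#'
#' \code{TAV = 1000 * content (g/100 g) / threshold (mg/100 g)} for each
#' residue with a defined taste threshold. Class totals: TFT sums the fresh
#' (umami) TAVs, TBT the bitter TAVs, and TST by default sums only the
#' \{Thr, Ser, Gly\} TAVs (the sweet-content class additionally includes Ala;
#' the sweet-TAV set is configurable via \code{sweet_tav_residues}). A
#' residue contributes significantly to flavour when its TAV is strictly
#' greater than 1.
#'
#' @param profile An [amino_acid_profile()].
#' @param sweet_tav_residues Residues summed into TST (default Thr, Ser, Gly).
#' @return List with \code{tav} (named vector), \code{significant} (logical,
#'   TAV > 1), and totals \code{tft}, \code{tbt}, \code{tst}.
#' @examples
#' p <- suppressWarnings(amino_acid_profile(c(Glu = 27.29)))
#' tav(p)$tav[["Glu"]]  # 909.67
#' @export
tav <- function(profile, sweet_tav_residues = c("Thr", "Ser", "Gly")) {
  stopifnot(inherits(profile, "aa_profile"))
  rt <- residue_table()
  has_thr <- !is.na(rt$taste_threshold)
  res <- rt$three_letter[has_thr]
  vals <- 1000 * profile$content[res] / rt$taste_threshold[has_thr]
  classes <- stats::setNames(rt$flavour_class[has_thr], res)
  sweet <- normalise_residue_names(sweet_tav_residues)
  list(
    tav = vals,
    significant = vals > 1,
    tft = sum(vals[classes == "fresh"]),
    tbt = sum(vals[classes == "bitter"]),
    tst = sum(vals[sweet])
  )
}

#' Full nutrition report for one profile
#'
#' Combines [aas()], [per()], [class_sums()] and [tav()] into one object.
#'
#' @param profile An [amino_acid_profile()].
#' @param reference Reference pattern for AAS.
#' @return A \code{nutrition_report} list with components \code{sample_id},
#'   \code{aas}, \code{limiting}, \code{per}, \code{sums}, \code{tav}.
#' @export
nutrition_report <- function(profile, reference = fao_who_adult_pattern()) {
  stopifnot(inherits(profile, "aa_profile"))
  a <- aas(profile, reference)
  structure(list(sample_id = profile$sample_id, aas = a$scores,
                 limiting = a$limiting, per = per(profile),
                 sums = class_sums(profile), tav = tav(profile)),
            class = "nutrition_report")
}

#' @export
print.nutrition_report <- function(x, ...) {
  cat(sprintf("<nutrition_report> %s\n", x$sample_id))
  cat(sprintf("  TAA %.2f  EAA %.2f (EAA/TAA %.2f%%)  HAA %.2f g/100 g\n",
              x$sums[["taa"]], x$sums[["eaa"]], x$sums[["eaa_taa"]],
              x$sums[["haa"]]))
  cat(sprintf("  PER1-3: %.2f / %.2f / %.2f\n",
              x$per[["per1"]], x$per[["per2"]], x$per[["per3"]]))
  cat(sprintf("  TFT %.2f  TBT %.2f  TST %.2f\n",
              x$tav$tft, x$tav$tbt, x$tav$tst))
  if (length(x$limiting))
    cat("  limiting amino acids: ", paste(utils::head(x$limiting, 2),
                                          collapse = ", "), "\n", sep = "")
  invisible(x)
}
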