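# Peptide physicochemistry, structure-activity motif flags, ingestion of
# external predictor score tables and threshold-based screening.

#' Peptide mass from residue masses
#'
#' Sum of residue masses plus one water (18.010565 Da monoisotopic,
#' 18.01528 Da average). Full precision is returned; round to 2 decimals when
#' comparing with published molecular-weight tables.
#'
#' @param sequence Residue string.
#' @param kind \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Mass in Da.
#' @examples
#' peptide_mass("WGF")  # 408.18
#' peptide_mass("PL")   # 228.15
#' @export
peptide_mass <- function(sequence, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  seq <- validate_sequence(sequence)
  rt <- residue_table()
  masses <- if (kind == "monoisotopic") rt$monoisotopic_mass else rt$average_mass
  names(masses) <- rt$one_letter
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(masses[chars]) + if (kind == "monoisotopic") WATER_MONO else WATER_AVG
}

#' Structure-activity motif flags of a peptide
#'
#' Flags the features associated with DPP-IV inhibitory potency: hydrophobic
#' residue content (set \{A, V, I, L, F, M, P\}), a hydrophobic N-terminal
#' residue, and proline at the N-terminus, the penultimate position
#' (\code{length - 1}) or the C-terminus. Positional flags of single-residue
#' peptides are \code{FALSE}; the hydrophobic fraction is always defined.
#'
#' @param sequence Residue string.
#' @return List with \code{hydrophobic_fraction} (0-1) and logical flags
#'   \code{n_term_hydrophobic}, \code{pro_n_terminal}, \code{pro_penultimate},
#'   \code{pro_c_terminal}.
#' @examples
#' motif_flags("QQPL")  # Pro penultimate
#' motif_flags("PAL")   # Pro N-terminal, fully hydrophobic
#' @export
motif_flags <- function(sequence) {
  seq <- validate_sequence(sequence)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hydro <- c("A", "V", "I", "L", "F", "M", "P")
  list(
    hydrophobic_fraction = mean(chars %in% hydro),
    n_term_hydrophobic = chars[1] %in% hydro,
    pro_n_terminal = n >= 2 && chars[1] == "P",
    pro_penultimate = n >= 2 && chars[n - 1L] == "P",
    pro_c_terminal = n >= 2 && chars[n] == "P"
  )
}

#' Build a peptide record table
#'
#' One row per sequence with length, monoisotopic and average mass and the
#' [motif_flags()] columns.
#'
#' @param sequences Character vector of residue strings.
#' @return data.frame with columns \code{sequence}, \code{length},
#'   \code{mono_mass}, \code{avg_mass}, \code{hydrophobic_fraction},
#'   \code{n_term_hydrophobic}, \code{pro_n_terminal}, \code{pro_penultimate},
#'   \code{pro_c_terminal}.
#' @export
peptide_records <- function(sequences) {
  stopifnot(length(sequences) >= 0)
  rows <- lapply(sequences, function(s) {
    fl <- motif_flags(s)
    data.frame(sequence = validate_sequence(s), length = nchar(s),
               mono_mass = peptide_mass(s, "monoisotopic"),
               avg_mass = peptide_mass(s, "average"),
               hydrophobic_fraction = fl$hydrophobic_fraction,
               n_term_hydrophobic = fl$n_term_hydrophobic,
               pro_n_terminal = fl$pro_n_terminal,
               pro_penultimate = fl$pro_penultimate,
               pro_c_terminal = fl$pro_c_terminal,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(sequence = character(), length = integer(),
                      mono_mass = numeric(), avg_mass = numeric(),
                      hydrophobic_fraction = numeric(),
                      n_term_hydrophobic = logical(),
                      pro_n_terminal = logical(), pro_penultimate = logical(),
                      pro_c_terminal = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Parse one numeric score cell. Accepts plain decimals, "8.90E-6",
# "8.90 × 10^−6" (with unicode multiplication sign/minus/superscripts) and
# treats "NA", "-", "" as explicitly missing. Returns NA_real_ for missing,
# stops for unparseable content.
parse_score_number <- function(x, line = NA_integer_, column = "") {
  x <- trimws(as.character(x))
  if (is.na(x) || x %in% c("NA", "-", "−", "")) return(NA_real_)
  # normalise unicode minus and multiplication sign forms
  x <- gsub("−", "-", x)
  x <- gsub("×", "x", x)
  x <- gsub("[[:space:]]", "", x)
  # a x 10^b -> aEb
  m <- regmatches(x, regexec("^(-?[0-9.]+)x10\\^?(-?[0-9]+)$", x))[[1]]
  if (length(m) == 3L) x <- paste0(m[2], "E", m[3])
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val))
    stop("unparseable numeric value '", x, "'",
         if (!is.na(line)) paste0(" at line ", line) else "",
         if (nzchar(column)) paste0(" in column ", column) else "")
  val
}

# Remove a trailing percent sign before numeric parsing.
parse_percent <- function(x, line = NA_integer_, column = "") {
  parse_score_number(sub("%$", "", trimws(as.character(x))), line, column)
}

#' Ingest an external predictor score table
#'
#' Reads a CSV of per-peptide predictor outputs (bioactivity score, DPP-IV
#' inhibition probability, allergenicity mark, Caco-2 log-permeability, MDCK
#' permeability, HIA band, plasma protein binding, BBB band, unbound
#' fraction). These scores come from external tools and are ingested as data,
#' never recomputed. \code{"NA"} and \code{"-"} cells become explicit
#' \code{NA}; MDCK values in either \code{8.90E-6} or \code{8.90 × 10^−6}
#' notation are parsed.
#'
#' Expected columns (extra columns pass through): \code{sequence},
#' \code{mol_weight_da}, \code{bioactivity}, \code{dppiv_probability},
#' \code{allergenic}, \code{caco2_log}, \code{mdck_cm_s}, \code{hia_band},
#' \code{ppb_percent}, \code{bbb_band}, \code{fu_percent}.
#'
#' @param path CSV path.
#' @return data.frame keyed by \code{sequence} with typed numeric columns.
#'   Duplicate sequences are an error.
#' @export
ingest_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) return(raw)
  if (!"sequence" %in% names(raw)) stop("score table must have a 'sequence' column")
  dup <- raw$sequence[duplicated(raw$sequence)]
  if (length(dup))
    stop("duplicate sequence(s) in score table: ", paste(unique(dup), collapse = ", "))
  out <- data.frame(sequence = vapply(raw$sequence, validate_sequence, "",
                                      USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  num_cols <- c("mol_weight_da", "bioactivity", "dppiv_probability", "caco2_log",
                "mdck_cm_s")
  pct_cols <- c("ppb_percent", "fu_percent")
  for (cn in intersect(num_cols, names(raw)))
    out[[cn]] <- vapply(seq_len(nrow(raw)), function(i)
      parse_score_number(raw[[cn]][i], line = i + 1L, column = cn), 0)
  for (cn in intersect(pct_cols, names(raw)))
    out[[cn]] <- vapply(seq_len(nrow(raw)), function(i)
      parse_percent(raw[[cn]][i], line = i + 1L, column = cn), 0)
  for (cn in intersect(c("allergenic", "hia_band", "bbb_band"), names(raw)))
    out[[cn]] <- trimws(raw[[cn]])
  if ("dppiv_probability" %in% names(out)) {
    p <- out$dppiv_probability
    bad_p <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad_p))
      stop("dppiv_probability outside [0, 1] at row(s) ",
           paste(bad_p, collapse = ", "))
  }
  out
}

#' Screening thresholds
#'
#' @param bioactivity_min Retain peptides with bioactivity strictly above this
#'   (default 0.5).
#' @param caco2_optimal_log Caco-2 log-permeability above which absorption is
#'   flagged optimal (default -5.15).
#' @param mdck_low,mdck_high MDCK permeability band bounds in cm/s (defaults
#'   2e-6 and 20e-6; boundaries belong to the medium band).
#' @param hia_cut HIA percentage below which absorption is flagged high
#'   (default 30).
#' @param dppiv_min Optional DPP-IV probability cut; default \code{NULL}
#'   applies no cut (the probability is reported, not thresholded).
#' @return A \code{screen_config} list.
#' @export
screen_config <- function(bioactivity_min = 0.5, caco2_optimal_log = -5.15,
                          mdck_low = 2e-6, mdck_high = 20e-6, hia_cut = 30,
                          dppiv_min = NULL) {
  stopifnot(is.finite(bioactivity_min), is.finite(caco2_optimal_log),
            is.finite(mdck_low), is.finite(mdck_high), is.finite(hia_cut),
            mdck_low < mdck_high)
  structure(list(bioactivity_min = bioactivity_min,
                 caco2_optimal_log = caco2_optimal_log,
                 mdck_low = mdck_low, mdck_high = mdck_high,
                 hia_cut = hia_cut, dppiv_min = dppiv_min),
            class = "screen_config")
}

#' Band an MDCK permeability value
#'
#' Low is below \code{mdck_low}, high strictly above \code{mdck_high};
#' boundary values fall in the medium band.
#'
#' @param mdck Permeability in cm/s (non-negative). Vectorised; \code{NA} in,
#'   \code{NA} out.
#' @param config A [screen_config()].
#' @return Character vector over \code{c("low", "medium", "high")}.
#' @examples
#' classify_permeability(8.9e-6)  # "medium"
#' @export
classify_permeability <- function(mdck, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (any(!is.na(mdck) & mdck < 0)) stop("MDCK permeability must be non-negative")
  ifelse(is.na(mdck), NA_character_,
         ifelse(mdck < config$mdck_low, "low",
                ifelse(mdck > config$mdck_high, "high", "medium")))
}

#' Screen peptides on ingested predictor scores
#'
#' Retains rows whose bioactivity score is strictly greater than
#' \code{config$bioactivity_min} (and, if \code{config$dppiv_min} is set,
#' whose DPP-IV probability exceeds it), then ranks by DPP-IV probability
#' descending with missing probabilities last; ties break by bioactivity
#' descending, then by sequence. Adds the MDCK permeability band, Caco-2
#' optimal flag and motif-flag columns.
#'
#' @param scores data.frame from [ingest_scores()] (must include
#'   \code{sequence} and \code{bioactivity}).
#' @param config A [screen_config()].
#' @return Ranked data.frame, a subset of the input rows with added columns
#'   \code{mdck_band}, \code{caco2_optimal}, masses and motif flags.
#' @export
screen_peptides <- function(scores, config = screen_config()) {
  stopifnot(is.data.frame(scores), inherits(config, "screen_config"))
  if (nrow(scores) == 0L) return(scores)
  if (!all(c("sequence", "bioactivity") %in% names(scores)))
    stop("scores must contain 'sequence' and 'bioactivity' columns")
  keep <- !is.na(scores$bioactivity) & scores$bioactivity > config$bioactivity_min
  if (!is.null(config$dppiv_min))
    keep <- keep & !is.na(scores$dppiv_probability) &
      scores$dppiv_probability > config$dppiv_min
  out <- scores[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  rec <- peptide_records(out$sequence)
  out <- cbind(out, rec[, setdiff(names(rec), "sequence"), drop = FALSE])
  if ("mdck_cm_s" %in% names(out))
    out$mdck_band <- classify_permeability(out$mdck_cm_s, config)
  if ("caco2_log" %in% names(out))
    out$caco2_optimal <- !is.na(out$caco2_log) &
      out$caco2_log > config$caco2_optimal_log
  p <- if ("dppiv_probability" %in% names(out)) out$dppiv_probability
       else rep(NA_real_, nrow(out))
  ord <- order(is.na(p), -ifelse(is.na(p), -Inf, p), -out$bioactivity,
               out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
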