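# End-to-end pipeline: digest -> mass/motif -> optional screen -> report,
# with a run manifest. This is the programmatic entry point; the same
# functions back the inst/exec/coixpep command-line wrapper.

#' Run the digestion-to-screening pipeline
#'
#' Digests every protein in \code{fasta} with the given enzymes, builds the
#' peptide record table (masses and motif flags), optionally joins an
#' external predictor score table and screens it, and writes
#' \code{peptides.csv}, \code{census.json}, \code{manifest.json} and (when
#' scores are supplied) \code{screened.csv} into \code{out_dir}. The output
#' equals composing [digest()], [census()], [peptide_records()] and
#' [screen_peptides()] by hand; there is no hidden state.
#'
#' @param fasta Path to the input FASTA.
#' @param out_dir Output directory (created if absent).
#' @param enzymes Character vector over \code{c("pepsin", "trypsin")} or a
#'   list of [cleavage_rule()] objects.
#' @param mode Digestion mode, \code{"concurrent"} or \code{"sequential"}.
#' @param scores Optional path to a predictor score CSV for
#'   [screen_peptides()].
#' @param config A [screen_config()].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return The output directory path, invisibly. On a stage failure, partial
#'   outputs are retained and the manifest names the failed stage.
#' @export
run_pipeline <- function(fasta, out_dir, enzymes = c("pepsin", "trypsin"),
                         mode = c("concurrent", "sequential"), scores = NULL,
                         config = screen_config(), seed = 1L) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "coixpep",
    version = as.character(utils::packageVersion("coixpep")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    mode = mode,
    config = unclass(config),
    inputs = list(fasta = list(path = fasta,
                               md5 = unname(tools::md5sum(fasta)))),
    counts = list(),
    status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  fail <- function(stage, e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  }

  rules <- tryCatch({
    if (is.character(enzymes)) {
      lapply(enzymes, function(e) switch(e,
        pepsin = pepsin_rule(), trypsin = trypsin_rule(),
        stop("unknown enzyme '", e, "'; supply a cleavage_rule instead")))
    } else enzymes
  }, error = function(e) fail("rules", e))

  results <- tryCatch({
    proteins <- read_fasta(fasta)
    lapply(proteins, digest, rules = rules, mode = mode)
  }, error = function(e) fail("digest", e))
  manifest$counts$proteins <- length(results)

  peptides <- tryCatch({
    tab <- peptide_records(unlist(lapply(results, function(r) r$peptides$sequence)))
    tab$source_id <- rep(vapply(results, `[[`, "", "source_id"),
                         vapply(results, function(r) nrow(r$peptides), 0L))
    write_peptide_table(tab, file.path(out_dir, "peptides.csv"))
    tab
  }, error = function(e) fail("peptides", e))
  manifest$counts$peptides <- nrow(peptides)

  cen <- tryCatch(census(results), error = function(e) fail("census", e))
  jsonlite::write_json(list(
    total_peptides = cen$total_peptides,
    dh_percent = cen$dh_percent,
    fraction_below_5 = cen$fraction_below(5),
    length_histogram = as.list(cen$length_histogram)
  ), file.path(out_dir, "census.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(scores)) {
    screened <- tryCatch({
      if (!file.exists(scores))
        stop("scores file not found (the 'scores' argument): ", scores)
      screen_peptides(ingest_scores(scores), config)
    }, error = function(e) fail("screen", e))
    utils::write.csv(screened, file.path(out_dir, "screened.csv"),
                     row.names = FALSE)
    manifest$counts$screened <- nrow(screened)
    manifest$inputs$scores <- list(path = scores,
                                   md5 = unname(tools::md5sum(scores)))
  }

  manifest$status <- "ok"
  write_manifest()
  invisible(out_dir)
}
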