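#' Run configuration for the end-to-end pipeline
#'
#' @param source_a,source_b paths to the two variant TSVs (LOVD-like and
#'   ClinVar-like dialects).
#' @param transcript_json,transcript_fasta transcript model files.
#' @param cas_library path to a Cas library JSON, or `NULL` for the packaged
#'   default.
#' @param outdir output directory.
#' @param col_map_a,col_map_b column mappings for [read_variant_table()].
#' @param precedence Cas precedence for single-Cas assignment.
#' @param top_n size of the most-reported table.
#' @param flank scan context width per side.
#' @return list of class `run_config`.
#' @export
run_config <- function(source_a, source_b, transcript_json, transcript_fasta,
                       outdir, cas_library = NULL,
                       col_map_a = NULL, col_map_b = NULL,
                       precedence = default_cas_precedence(),
                       top_n = 10L, flank = 26L) {
  structure(list(source_a = source_a, source_b = source_b,
                 transcript_json = transcript_json,
                 transcript_fasta = transcript_fasta,
                 cas_library = cas_library, outdir = outdir,
                 col_map_a = col_map_a, col_map_b = col_map_b,
                 precedence = precedence, top_n = as.integer(top_n),
                 flank = as.integer(flank)),
            class = "run_config")
}

default_col_map <- function() {
  c(gene = "gene", hgvs_c = "hgvs_c", significance = "significance",
    times_reported = "times_reported", flagged = "flagged")
}

#' Run the full analysis pipeline
#'
#' ingest (read + merge + harmonize) -> classify (consequence + editability)
#' -> scan (PAM/window placements + single-Cas assignment) -> report. All
#' stage outputs are written as inspectable TSV/JSON under `config$outdir`;
#' a `manifest.json` records the configuration and content hashes. The run is
#' deterministic: identical inputs give byte-identical outputs.
#'
#' @param config [run_config()].
#' @return invisibly, a list with `records`, `assignments`, `placements`,
#'   `report`, and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("source_a", "source_b", "transcript_json", "transcript_fasta"))
    if (!file.exists(config[[f]]))
      stop("ingest: input file not found: ", config[[f]], " (", f, ")")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  entries <- rbind(
    read_variant_table(config$source_a, "lovd",
                       config$col_map_a %||% default_col_map()),
    read_variant_table(config$source_b, "clinvar",
                       config$col_map_b %||% default_col_map()))
  records <- merge_sources(entries)

  model <- read_transcript(config$transcript_json, config$transcript_fasta)
  library <- if (is.null(config$cas_library)) default_cas_library()
             else read_cas_library(config$cas_library)

  analyzed <- select_for_analysis(records)
  analyzed <- annotate_consequence(analyzed, model)
  analyzed <- annotate_editability(analyzed)

  # fold annotation back into the full record table for reporting
  records$consequence <- NA_character_
  records$exon <- NA_integer_
  records$codon_number <- NA_integer_
  records <- annotate_editability(records)
  m <- match(analyzed$key, records$key)
  records$consequence[m] <- analyzed$consequence
  records$exon[m] <- analyzed$exon
  records$codon_number[m] <- analyzed$codon_number

  scan <- scan_cohort(analyzed, model, library,
                      precedence = config$precedence, flank = config$flank)

  report <- summarize_cohort(records, model, scan$assignments,
                             top_n = config$top_n)

  write_variant_records(records, file.path(config$outdir, "variants.tsv"),
                        file.path(config$outdir, "variants.jsonl"))
  utils::write.table(scan$assignments,
                     file.path(config$outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$placements,
                     file.path(config$outdir, "placements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(report, file.path(config$outdir, "report"))

  manifest <- list(
    tool = "bescan",
    version = as.character(utils::packageVersion("bescan")),
    config = config[c("source_a", "source_b", "transcript_json",
                      "transcript_fasta", "cas_library", "precedence",
                      "top_n", "flank")],
    input_md5 = as.list(tools::md5sum(unlist(config[c(
      "source_a", "source_b", "transcript_json", "transcript_fasta")]))),
    n_records = nrow(records), n_analyzed = nrow(analyzed))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, analyzed = analyzed,
                 assignments = scan$assignments, placements = scan$placements,
                 report = report, outdir = config$outdir))
}

#' Write a simulated cohort to disk
#'
#' Emits the two source TSVs, the transcript JSON+FASTA, and the ground-truth
#' table into `outdir`, ready for [run_pipeline()].
#'
#' @param outdir output directory.
#' @param spec [cohort_spec()].
#' @param model transcript model, or `NULL` to generate one with
#'   [make_transcript()] under the spec's seed.
#' @return invisibly, named paths.
#' @export
simulate_cohort <- function(outdir, spec = cohort_spec(), model = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(model))
    model <- make_transcript(n_exons = 12, seed = spec$seed,
                             name = paste0(spec$gene, "_tx"))
  cohort <- make_cohort(spec, model)
  paths <- c(source_a = file.path(outdir, "source_a_lovd_like.tsv"),
             source_b = file.path(outdir, "source_b_clinvar_like.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             transcript_json = file.path(outdir, "transcript.json"),
             transcript_fasta = file.path(outdir, "transcript.fa"))
  utils::write.table(cohort$source_a, paths["source_a"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$source_b, paths["source_b"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_transcript(model, paths["transcript_json"], paths["transcript_fasta"])
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `run` (full pipeline),
#' and `report` (re-summarize a previous run's outputs are covered by `run`).
#' Installed as `inst/scripts/bescan`; flags are `--key value` pairs mirroring
#' [run_config()] and [cohort_spec()].
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
bescan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bescan <simulate|run> [--key value ...]",
    "  simulate --outdir DIR [--n N] [--seed S]",
    "  run --source-a A.tsv --source-b B.tsv --transcript-json T.json",
    "      --transcript-fasta T.fa --outdir DIR [--cas-library L.json]",
    "      [--top-n N]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i + 1 > length(args))
      stop("malformed arguments near '", args[i], "'\n", usage)
    opts[[sub("^--", "", args[i])]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      spec <- cohort_spec(
        n_variants = as.integer(opts$n %||% 1115),
        seed = as.integer(opts$seed %||% 1))
      simulate_cohort(opts$outdir %||% stop("simulate: --outdir required"),
                      spec)
      message("simulated cohort written to ", opts$outdir)
      0L
    } else if (cmd == "run") {
      cfg <- run_config(
        source_a = opts[["source-a"]] %||% stop("run: --source-a required"),
        source_b = opts[["source-b"]] %||% stop("run: --source-b required"),
        transcript_json = opts[["transcript-json"]] %||%
          stop("run: --transcript-json required"),
        transcript_fasta = opts[["transcript-fasta"]] %||%
          stop("run: --transcript-fasta required"),
        outdir = opts$outdir %||% stop("run: --outdir required"),
        cas_library = opts[["cas-library"]],
        top_n = as.integer(opts[["top-n"]] %||% 10))
      res <- run_pipeline(cfg)
      print(res$report)
      0L
    } else {
      message("unknown subcommand '", cmd, "'\n", usage)
      1L
    }
  }, error = function(e) {
    message("bescan: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
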