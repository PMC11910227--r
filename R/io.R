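#' Read and write gene-set collections in GMT format
#'
#' `read_gmt()` parses a tab-separated GMT file (set name, description, then
#' member genes, one set per line) into a named list via the fgsea reader;
#' `write_gmt()` writes such a list back out (description column set to the
#' set name).
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Serializes the cohort to the pipeline's on-disk interchange formats:
#' `beta.csv` (probe x sample beta values), `counts.tsv` (gene, length, then
#' one column per sample), `annotation.tsv`, `gene_sets.gmt`,
#' `sample_sheet.csv`, `clinical.csv`, `ihc.csv` and `truth.json` (planted
#' truth, including the true cell fractions). With
#' `include_reference = TRUE` the deconvolution reference
#' (`reference.tsv`), tumor-vs-normal compendium (`tumor_normal.tsv`) and
#' per-sample QC matrices are written as well, which is what
#' [run_pipeline()] needs to run every stage from disk.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param directory Output directory (created if absent).
#' @param include_reference Also write the reference, tumor-vs-normal and QC
#'   fixtures (default FALSE).
#' @return A manifest tibble with `file`, `path`, `bytes`, `md5`.
#' @export
write_fixtures <- function(cohort, directory, include_reference = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)

  readr::write_csv(cohort$beta, p("beta.csv"))
  counts_out <- dplyr::left_join(cohort$gene_lengths, cohort$counts,
                                 by = "gene_id")
  readr::write_tsv(counts_out, p("counts.tsv"))
  readr::write_tsv(cohort$annotation, p("annotation.tsv"))
  write_gmt(cohort$gene_sets, p("gene_sets.gmt"))
  readr::write_csv(cohort$sample_sheet, p("sample_sheet.csv"))
  readr::write_csv(cohort$clinical, p("clinical.csv"))
  readr::write_csv(cohort$ihc, p("ihc.csv"))
  truth <- cohort$truth
  truth$true_fractions <- cohort$true_fractions
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c("beta.csv", "counts.tsv", "annotation.tsv", "gene_sets.gmt",
             "sample_sheet.csv", "clinical.csv", "ihc.csv", "truth.json")
  if (include_reference) {
    readr::write_tsv(cohort$reference, p("reference.tsv"))
    readr::write_tsv(cohort$tumor_normal, p("tumor_normal.tsv"))
    readr::write_csv(cohort$detection_p, p("detection_p.csv"))
    readr::write_csv(cohort$bead_count, p("bead_count.csv"))
    files <- c(files, "reference.tsv", "tumor_normal.tsv",
               "detection_p.csv", "bead_count.csv")
  }
  paths <- file.path(directory, files)
  tibble(file = files, path = paths,
         bytes = file.size(paths),
         md5 = unname(tools::md5sum(paths)))
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param directory Directory holding the fixture files.
#' @return A list with the same elements as a [simulate_cohort()] result
#'   (minus the configuration); optional files are NULL when absent.
#' @export
read_fixtures <- function(directory) {
  p <- function(f) file.path(directory, f)
  opt <- function(f, reader) if (file.exists(p(f))) reader(p(f)) else NULL
  counts_in <- readr::read_tsv(p("counts.tsv"), show_col_types = FALSE)
  truth <- opt("truth.json", function(f) jsonlite::read_json(f, simplifyVector = TRUE))
  out <- list(
    beta = readr::read_csv(p("beta.csv"), show_col_types = FALSE),
    counts = dplyr::select(counts_in, -"length_bp"),
    gene_lengths = dplyr::select(counts_in, "gene_id", "length_bp"),
    annotation = readr::read_tsv(p("annotation.tsv"), show_col_types = FALSE),
    gene_sets = read_gmt(p("gene_sets.gmt")),
    sample_sheet = readr::read_csv(p("sample_sheet.csv"), show_col_types = FALSE),
    clinical = readr::read_csv(p("clinical.csv"), show_col_types = FALSE),
    ihc = readr::read_csv(p("ihc.csv"), show_col_types = FALSE),
    truth = truth,
    reference = opt("reference.tsv",
                    function(f) readr::read_tsv(f, show_col_types = FALSE)),
    tumor_normal = opt("tumor_normal.tsv",
                       function(f) readr::read_tsv(f, show_col_types = FALSE)),
    detection_p = opt("detection_p.csv",
                      function(f) readr::read_csv(f, show_col_types = FALSE)),
    bead_count = opt("bead_count.csv",
                     function(f) readr::read_csv(f, show_col_types = FALSE)))
  if (!is.null(out$truth$true_fractions)) {
    out$true_fractions <- tibble::as_tibble(out$truth$true_fractions)
    out$truth$true_fractions <- NULL
  }
  out
}
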