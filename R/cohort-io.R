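# Plain-text serialization of a cohort: metadata CSV, per-participant
# matrix CSVs, long-format TSV, volumes CSV, microstructure CSV, template
# CSV, and a JSON sidecar with the generating configuration. All files
# UTF-8; round-trips are byte-stable.

#' Write a cohort to a directory of plain-text files
#'
#' @param cohort A `cohort` object from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "matrices"), showWarnings = FALSE)
  write.csv(cohort$records, file.path(dir, "participants.csv"), row.names = FALSE)
  for (id in names(cohort$matrices)) {
    write.csv(cohort$matrices[[id]], file.path(dir, "matrices", paste0(id, ".csv")))
  }
  long <- do.call(rbind, lapply(names(cohort$matrices), function(id) {
    x <- matrix_to_long(cohort$matrices[[id]])
    cbind(participant_id = id, x[, c("region_a", "region_b", "gfa")])
  }))
  write_tsv(long, file.path(dir, "tracts_long.tsv"))
  write.csv(cohort$volumes, file.path(dir, "volumes.csv"), row.names = FALSE)
  write.csv(cohort$micro, file.path(dir, "microstructure.csv"), row.names = FALSE)
  write.csv(cohort$template, file.path(dir, "template.csv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `cohort` object (without the generator `truth` element).
#' @export
read_cohort <- function(dir) {
  records <- read.csv(file.path(dir, "participants.csv"), stringsAsFactors = FALSE)
  records$phenotype <- factor(records$phenotype, levels = PHENOTYPE_LEVELS)
  records$group <- factor(records$group, levels = GROUP_LEVELS)
  records$sex <- factor(records$sex, levels = c("F", "M"))
  files <- sort(list.files(file.path(dir, "matrices"), pattern = "\\.csv$",
                           full.names = TRUE))
  matrices <- lapply(files, read_matrix_csv)
  names(matrices) <- sub("\\.csv$", "", basename(files))
  for (id in names(matrices)) validate_connectivity_matrix(matrices[[id]], id)
  template <- read_matrix_csv(file.path(dir, "template.csv"))
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path, simplifyVector = TRUE) else NULL
  structure(list(
    records = records, matrices = matrices,
    volumes = read.csv(file.path(dir, "volumes.csv"), stringsAsFactors = FALSE),
    micro = read.csv(file.path(dir, "microstructure.csv"), stringsAsFactors = FALSE),
    template = template, config = config, truth = NULL
  ), class = "cohort")
}

# Labelled symmetric matrix CSV reader.
read_matrix_csv <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

# TSV writer used for all tabular outputs; optional provenance header
# lines are prefixed with '#'.
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
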