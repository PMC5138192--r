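## Plain-text I/O: key = value configuration files and tab-delimited tables
## with provenance comment headers.

#' @include AllClasses.R
NULL

## Parse "key = value" lines; '#' starts a comment, blank lines ignored.
.parseKeyValue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, `[`, character(1), 2))
}

.cfgNum <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

#' Read a selection protocol from a key = value config file
#'
#' Recognized keys (all optional, falling back to the defaults of
#' \code{\link{SelectionProtocol}}): \code{mutation_rate},
#' \code{generations_per_step}, \code{enrichment_factor}, \code{n_steps},
#' \code{colonies_sampled}. Lines starting with \code{#} are comments.
#'
#' @param path Path to the config file.
#' @return A \code{\link{SelectionProtocol}}.
#' @export
readProtocolConfig <- function(path) {
  cfg <- .parseKeyValue(path)
  SelectionProtocol(
    mutationRate = .cfgNum(cfg, "mutation_rate", 1e-8),
    generationsPerStep = .cfgNum(cfg, "generations_per_step", 45),
    enrichmentFactor = .cfgNum(cfg, "enrichment_factor", 100),
    nSteps = .cfgNum(cfg, "n_steps", 3),
    coloniesSampled = .cfgNum(cfg, "colonies_sampled", 10)
  )
}

#' Read a simulation configuration from a key = value config file
#'
#' Recognized keys: \code{inoculum_titer}, \code{stationary_titer},
#' \code{wt_death_survival}, \code{wt_death_survival_no_lca},
#' \code{mutant_survival_multiplier}, \code{dilution_factor},
#' \code{culture_volume}, \code{n_replicates}, \code{dilution_method}.
#'
#' @param path Path to the config file.
#' @return A \code{\link{SimulationConfig}}.
#' @export
readSimulationConfig <- function(path) {
  cfg <- .parseKeyValue(path)
  SimulationConfig(
    inoculumTiter = .cfgNum(cfg, "inoculum_titer", 1e5),
    stationaryTiter = .cfgNum(cfg, "stationary_titer", 2e8),
    wtDeathSurvival = .cfgNum(cfg, "wt_death_survival", 1e-2),
    wtDeathSurvivalNoLCA = .cfgNum(cfg, "wt_death_survival_no_lca", 1e-4),
    mutantSurvivalMultiplier = .cfgNum(cfg, "mutant_survival_multiplier",
                                       100),
    dilutionFactor = .cfgNum(cfg, "dilution_factor", 100),
    cultureVolume = .cfgNum(cfg, "culture_volume", 1),
    nReplicates = .cfgNum(cfg, "n_replicates", 1000),
    dilutionMethod = if (is.null(cfg[["dilution_method"]])) "binomial"
                     else cfg[["dilution_method"]]
  )
}

## Write a data.frame as TSV with '#' provenance header lines.
.writeTSV <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(
    sprintf("# hormevol %s", as.character(utils::packageVersion("hormevol"))),
    sprintf("# %s", meta)
  )
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Read a TSV written by .writeTSV (or any '#'-commented TSV).
.readTSV <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an enrichment trajectory as a delimited table
#'
#' Columns: \code{step}, \code{raw_fraction}, \code{capped_fraction},
#' \code{expected_mutants}, \code{detection_probability}; provenance
#' (package version and protocol parameters) in \code{#} header lines.
#'
#' @param trajectory An \code{\link{EnrichmentTrajectory}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "EnrichmentTrajectory"))
  p <- trajectory@protocol
  .writeTSV(as.data.frame(trajectory), path, meta = sprintf(
    "mu=%g generations=%g enrichment=%g steps=%d colonies=%d sample_size=%g",
    p@mutationRate, p@generationsPerStep, p@enrichmentFactor, p@nSteps,
    p@coloniesSampled, trajectory@sampleSize))
}

#' Read or write viability count tables
#'
#' Tab-delimited with columns \code{strain}, \code{replicate}, \code{day},
#' \code{total_cells_per_ml}, \code{viable_cells_per_ml}; \code{#} lines
#' are comments.
#'
#' @param path File path.
#' @param records data.frame of count records (for writing).
#' @param meta Character vector of provenance lines (for writing).
#' @return \code{readCountTable}: the records data.frame;
#'   \code{writeCountTable}: the path, invisibly.
#' @export
readCountTable <- function(path) {
  .validateCountRecords(.readTSV(path))
}

#' @rdname readCountTable
#' @export
writeCountTable <- function(records, path, meta = character()) {
  .writeTSV(.validateCountRecords(as.data.frame(records)), path, meta)
}

#' Read or write tetrad phenotype tables
#'
#' Tab-delimited with columns \code{tetrad_id}, \code{spore1} ..
#' \code{spore4}, spore values \code{long} or \code{short}.
#'
#' @param path File path.
#' @param tetrads A \code{\link{TetradDataset}} (for writing).
#' @param meta Character vector of provenance lines (for writing).
#' @return \code{readTetradTable}: a \code{\link{TetradDataset}};
#'   \code{writeTetradTable}: the path, invisibly.
#' @export
readTetradTable <- function(path) {
  df <- .readTSV(path)
  need <- c("tetrad_id", paste0("spore", 1:4))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tetrad table lacks column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, paste0("spore", 1:4)])
  if (!all(m %in% c("long", "short")))
    stop("spore values must be 'long' or 'short'")
  TetradDataset(m == "long")
}

#' @rdname readTetradTable
#' @export
writeTetradTable <- function(tetrads, path, meta = character()) {
  stopifnot(is(tetrads, "TetradDataset"))
  m <- ifelse(tetrads@spores, "long", "short")
  df <- data.frame(tetrad_id = seq_len(nrow(m)), m)
  names(df) <- c("tetrad_id", paste0("spore", 1:4))
  .writeTSV(df, path, meta)
}

#' Write a survival curve as a delimited table
#'
#' Columns: \code{day}, \code{mean_percent}, \code{sem}.
#'
#' @param curve A \code{\link{SurvivalCurve}}.
#' @param path Output path.
#' @param meta Character vector of provenance lines.
#' @return The path, invisibly.
#' @export
writeCurveTable <- function(curve, path, meta = character()) {
  stopifnot(is(curve, "SurvivalCurve"))
  df <- data.frame(day = curve@days, mean_percent = curve@viability,
                   sem = curve@sem)
  .writeTSV(df, path, meta = c(sprintf("strain=%s replicates=%d reference_day=%g",
                                       curve@strain, curve@nReplicates,
                                       curve@referenceDay), meta))
}
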