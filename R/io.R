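.REQUIRED_COLS <- c("animal_id", "sex", "age_months", "grip_g",
                    "hindlimb_mass_mg", "treadmill_s")
.OPTIONAL_NUM <- c("body_weight_g", "lean_mass_g", "fat_mass_g",
                   "peak_force_mN", "pcsa_mm2")

#' Read a phenotype cohort from delimited text
#'
#' Comma-separated UTF-8 with a header; missing values are empty fields.
#' Required columns: `animal_id`, `sex`, `age_months`, `grip_g`,
#' `hindlimb_mass_mg`, `treadmill_s` (treadmill may be missing per animal);
#' optional numeric columns `body_weight_g`, `lean_mass_g`, `fat_mass_g`,
#' `peak_force_mN`, `pcsa_mm2`. Row-level problems (non-numeric
#' measurements, non-positive values, unknown sex labels) are reported with
#' line numbers.
#'
#' @param path File path.
#' @return A phenotype `data.frame`.
#' @export
readCohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  missingCols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missingCols))
    stop(sprintf("schema error: missing required column(s) %s",
                 paste(missingCols, collapse = ", ")))
  problems <- character()
  numCols <- c("age_months", "grip_g", "hindlimb_mass_mg", "treadmill_s",
               intersect(.OPTIONAL_NUM, names(df)))
  for (cl in numCols) {
    raw <- df[[cl]]
    empty <- is.na(raw) | raw == ""
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(val))
    if (length(bad))
      problems <- c(problems, sprintf("line %d: non-numeric %s '%s'",
                                      bad + 1L, cl, raw[bad]))
    nonpos <- which(!is.na(val) & val <= 0)
    if (length(nonpos))
      problems <- c(problems, sprintf("line %d: non-positive %s (%s)",
                                      nonpos + 1L, cl, raw[nonpos]))
    df[[cl]] <- val
  }
  badSex <- which(!df$sex %in% c("male", "female"))
  if (length(badSex))
    problems <- c(problems, sprintf("line %d: sex '%s' not male/female",
                                    badSex + 1L, df$sex[badSex]))
  mandatoryNA <- which(is.na(df$age_months) | is.na(df$grip_g) |
                       is.na(df$hindlimb_mass_mg))
  if (length(mandatoryNA))
    problems <- c(problems,
                  sprintf("line %d: missing age, grip or mass", mandatoryNA + 1L))
  if (length(problems))
    stop("parse error(s) in ", path, ":\n  ",
         paste(utils::head(problems, 10L), collapse = "\n  "))
  df
}

#' Write a phenotype cohort as delimited text
#'
#' @param cohort Phenotype `data.frame`.
#' @param path Output path.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read/write a protein-abundance matrix (rows = proteins, columns = samples)
#'
#' Comma-separated with the protein id in the first column.
#'
#' @param path File path.
#' @return Numeric matrix with protein row names.
#' @export
readProteinMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readProteinMatrix
#' @param mat Numeric matrix (proteins x samples).
#' @export
writeProteinMatrix <- function(mat, path) {
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-trait table
#'
#' Comma-separated, one row per sample: `sample_id`, `cohort`, and the
#' numeric trait columns `grip`, `mass`, `treadmill`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
readTraitTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", .MEASUREMENTS)
  missingCols <- setdiff(need, names(df))
  if (length(missingCols))
    stop(sprintf("schema error: trait table missing column(s) %s",
                 paste(missingCols, collapse = ", ")))
  df
}

#' Read a key-value pipeline configuration file
#'
#' Plain text, one `key = value` pair per line, `#` comments. Recognized
#' keys (all optional, defaults in parentheses): `alpha` (0.05), `trend`
#' (0.1), `policy` (available), `rounding` (none), `young_lo`/`young_hi`
#' (4/9), `miss_treadmill` (0.19), `n_mc` (1e5), `seed` (1).
#'
#' @param path File path, or `NULL` for all defaults.
#' @return Named list of settings.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- list(alpha = 0.05, trend = 0.1, policy = "available",
              rounding = "none", young_lo = 4, young_hi = 9,
              miss_treadmill = 0.19, n_mc = 1e5, seed = 1L)
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop(sprintf("config line not of the form key = value: '%s'", ln))
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (is.na(num)) val else num
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$trend <= 0 || cfg$trend >= 1)
    stop("alpha and trend must lie in (0, 1)")
  if (cfg$trend <= cfg$alpha) stop("trend threshold must exceed alpha")
  if (!cfg$policy %in% c("available", "complete"))
    stop("policy must be 'available' or 'complete'")
  if (!cfg$rounding %in% c("none", "integer"))
    stop("rounding must be 'none' or 'integer'")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.cliLog <- function(outPrefix, cfg, extra = list()) {
  log <- c(sprintf("tool: sarcomice %s", as.character(packageVersion("sarcomice"))),
           sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           sprintf("config: %s",
                   paste(sprintf("%s=%s", names(cfg), unlist(cfg)),
                         collapse = " ")),
           vapply(names(extra), function(k)
             sprintf("%s: %s", k, extra[[k]]), character(1)))
  writeLines(log, paste0(outPrefix, ".log"))
}

.cliArgs <- function(args) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      out[[substring(a, 3)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `classify`, `prevalence`,
#' `compare`, and `genesets`; each reads delimited inputs, writes delimited
#' outputs plus a `.log` run record (tool version, configuration, seeds),
#' and returns a nonzero status with a one-line diagnostic on contract
#' errors. Installed as the `sarcomice` script under the package's `exec`
#' directory.
#'
#' Flags common to several subcommands: `--config` (key-value file, see
#' [readPipelineConfig()]), `--seed`, `--alpha`, `--trend`,
#' `--policy available|complete`, `--rounding none|integer`, `--out`
#' (output prefix).
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--sex male|female [--n N] --seed S --out prefix`:
#'     writes `<prefix>.csv`, a synthetic phenotype cohort.}
#'   \item{classify}{`--cohort file [--cutoffs g,mg,s] --out prefix`: derives
#'     cutoffs from the young animals (or uses the given fixed cutoffs) and
#'     writes the staged table `<prefix>.csv` and the cutoff report
#'     `<prefix>_cutoffs.csv`.}
#'   \item{prevalence}{`--staged file [--by bracket|pooled] --out prefix`:
#'     writes the prevalence table `<prefix>.csv` from a `classify` output.}
#'   \item{compare}{`--cohort file --measurement grip|mass|treadmill
#'     --groupby stage|bracket --out prefix`: stages the cohort, runs the
#'     decision tree on the chosen measurement across groups, writes the
#'     pairwise table and the decision path into the log.}
#'   \item{genesets}{`--matrix file --traits file --gmt file --trait name
#'     --out prefix`: per-protein associations in each cohort plus the
#'     main-effect gene-set screen, written as `<prefix>.csv`.}
#' }
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
sarcoMiceCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: sarcomice <simulate|classify|prevalence|compare|genesets> [flags]")
    cmd <- args[[1]]
    opt <- .cliArgs(args[-1])
    cfg <- readPipelineConfig(opt$config)
    for (k in c("alpha", "trend", "seed"))
      if (!is.null(opt[[k]])) cfg[[k]] <- as.numeric(opt[[k]])
    for (k in c("policy", "rounding"))
      if (!is.null(opt[[k]])) cfg[[k]] <- opt[[k]]
    cfg$seed <- as.integer(cfg$seed)
    out <- opt$out
    if (is.null(out)) stop("--out prefix is required")
    switch(cmd,
      simulate = .cliSimulate(opt, cfg, out),
      classify = .cliClassify(opt, cfg, out),
      prevalence = .cliPrevalence(opt, cfg, out),
      compare = .cliCompare(opt, cfg, out),
      genesets = .cliGenesets(opt, cfg, out),
      stop(sprintf("unknown subcommand '%s'", cmd)))
    0L
  }, error = function(e) {
    message("sarcomice: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cliSimulate <- function(opt, cfg, out) {
  sex <- if (is.null(opt$sex)) "male" else opt$sex
  n <- if (is.null(opt$n)) NULL else as.integer(opt$n)
  config <- defaultCohortConfig(sex, n = n, seed = cfg$seed)
  config@missTreadmill <- cfg$miss_treadmill
  cohort <- suppressWarnings(generateCohort(config))
  writeCohort(cohort, paste0(out, ".csv"))
  .cliLog(out, cfg, list(subcommand = "simulate", sex = sex,
                         animals = nrow(cohort)))
}

.cliClassify <- function(opt, cfg, out) {
  cohort <- readCohort(opt$cohort)
  sex <- unique(cohort$sex)
  if (length(sex) != 1L)
    stop("cohort mixes sexes; classify one sex at a time")
  if (!is.null(opt$cutoffs)) {
    v <- as.numeric(strsplit(opt$cutoffs, ",")[[1]])
    cuts <- fixedCutoffs(sex, v[1], v[2], v[3])
  } else {
    cuts <- deriveCutoffs(cohort, sex,
                          ageWindow = c(cfg$young_lo, cfg$young_hi),
                          rounding = cfg$rounding)
  }
  staged <- stageCohort(cohort, cuts, policy = cfg$policy)
  write.csv(as.data.frame(staged), paste0(out, ".csv"),
            row.names = FALSE, quote = FALSE, na = "")
  norms <- referenceNorms(cuts)
  norms$cutoff <- cutoffValues(cuts)[norms$measurement]
  write.csv(norms, paste0(out, "_cutoffs.csv"), row.names = FALSE,
            quote = FALSE)
  .cliLog(out, cfg, list(subcommand = "classify",
                         cutoffs = paste(round(cutoffValues(cuts), 3),
                                         collapse = ",")))
}

.cliPrevalence <- function(opt, cfg, out) {
  df <- read.csv(opt$staged, stringsAsFactors = FALSE)
  need <- c("stage", "pattern", "bracket")
  if (!all(need %in% names(df)))
    stop("input is not a classify output (stage/pattern/bracket columns required)")
  by <- if (is.null(opt$by)) "bracket" else opt$by
  staged <- .rehydrateStaged(df)
  write.csv(prevalenceTable(staged, by), paste0(out, ".csv"),
            row.names = FALSE, quote = FALSE)
  .cliLog(out, cfg, list(subcommand = "prevalence", by = by))
}

## Rebuild a StagedCohort from a flattened classify output.
.rehydrateStaged <- function(df) {
  sex <- unique(df$sex)
  cuts <- fixedCutoffs(sex, 1, 1, 1)  # placeholder; labels already computed
  new("StagedCohort",
      records = df[, intersect(names(df), c(.REQUIRED_COLS, .OPTIONAL_NUM))],
      flags = df[, c("G", "M", "T")],
      deficitCount = as.integer(df$deficit_count),
      evaluatedCount = as.integer(df$evaluated_count),
      stage = factor(df$stage, levels = .STAGES),
      pattern = factor(df$pattern, levels = .PATTERNS),
      bracket = as.character(df$bracket), cutoffs = cuts,
      policy = if (anyNA(df$stage)) "complete" else "available")
}

.cliCompare <- function(opt, cfg, out) {
  if (is.null(opt$measurement)) stop("--measurement is required")
  df <- read.csv(opt$cohort, stringsAsFactors = FALSE)
  groupby <- if (is.null(opt$groupby)) "stage" else opt$groupby
  if (!groupby %in% names(df))
    stop(sprintf("grouping column '%s' not in input (run classify first)",
                 groupby))
  col <- .measurementColumn(opt$measurement)
  keep <- !is.na(df[[col]]) & !is.na(df[[groupby]])
  groups <- split(df[[col]][keep], df[[groupby]][keep])
  res <- compareGroups(groups, alpha = cfg$alpha, trend = cfg$trend)
  write.csv(pairwiseResults(res), paste0(out, ".csv"), row.names = FALSE,
            quote = FALSE)
  .cliLog(out, cfg, list(subcommand = "compare",
                         omnibus = sprintf("%s p=%.4g",
                                           omnibusResult(res)$test,
                                           omnibusResult(res)$p),
                         path = paste(decisionPath(res), collapse = " | ")))
}

.cliGenesets <- function(opt, cfg, out) {
  mat <- readProteinMatrix(opt$matrix)
  traits <- readTraitTable(opt$traits)
  sets <- readGMT(opt$gmt)
  trait <- if (is.null(opt$trait)) "mass" else opt$trait
  assoc <- perProteinAssociation(mat, traits, traitNames = trait)
  res <- mainEffectScreen(assoc[assoc$cohort == "young", ],
                          assoc[assoc$cohort == "old", ], sets,
                          qThreshold = cfg$alpha)
  write.csv(res, paste0(out, ".csv"), row.names = FALSE)
  .cliLog(out, cfg, list(subcommand = "genesets", trait = trait,
                         flagged = sum(res$mainEffect)))
}
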