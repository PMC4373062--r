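## Orchestration: simulate -> scan -> date -> score -> cluster as one
## reproducible run. Configuration is a plain list validated up front (all
## problems collected, not just the first); every output is a deterministic
## function of the inputs and the seed.

.defaultConfig <- function() {
  list(seed = 1L,
       outDir = file.path(tempdir(), "ervclock_run"),
       input = NULL,              # FASTA of contigs to scan
       simulate = NULL,           # parameter grid for generateDataset
       dateOnly = NULL,           # TSV with a D column: re-date and stop
       polReference = NULL,       # protein FASTA/string for defect scoring
       ratePanel = defaultRatePanel(),
       scan = list(),             # ltrScanConfig overrides
       cluster = list(threshold = 0.15, model = "p"),
       precision = list(ages = 3L, dist = 3L))
}

#' Validate and resolve a pipeline configuration
#'
#' Fills defaults (including the standard three-rate panel and all scan
#' thresholds) and collects every schema violation instead of failing on the
#' first. Unknown keys produce warnings, not errors, for forward
#' compatibility.
#'
#' @param config named list of overrides (may be empty).
#' @return list with elements \code{config} (resolved), \code{errors}
#'   (character, empty when valid) and \code{warnings}.
#' @examples
#' validateConfig(list())$config$ratePanel
#' @export
validateConfig <- function(config = list()) {
  def <- .defaultConfig()
  errors <- character(0)
  warnings <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    warnings <- c(warnings, sprintf("unknown config key(s) ignored: %s",
                                    paste(unknown, collapse = ", ")))
  cfg <- def
  for (k in intersect(names(config), names(def))) {
    if (k %in% c("scan", "cluster", "precision") && is.list(config[[k]])) {
      cfg[[k]][names(config[[k]])] <- config[[k]]
    } else cfg[[k]] <- config[[k]]
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    errors <- c(errors, "seed must be a single number")
  rp <- cfg$ratePanel
  if (is.list(rp) && !is.data.frame(rp)) rp <- as.data.frame(rp)
  if (!is.data.frame(rp) || !all(c("label", "rate") %in% names(rp)))
    errors <- c(errors, "ratePanel must have columns 'label' and 'rate'")
  else {
    if (any(!is.finite(rp$rate) | rp$rate <= 0))
      errors <- c(errors, "all ratePanel rates must be positive")
    cfg$ratePanel <- rp
  }
  badScan <- setdiff(names(cfg$scan), names(formals(ltrScanConfig)))
  if (length(badScan))
    warnings <- c(warnings, sprintf("unknown scan key(s) ignored: %s",
                                    paste(badScan, collapse = ", ")))
  cfg$scan <- cfg$scan[setdiff(names(cfg$scan), badScan)]
  th <- cfg$cluster$threshold
  if (!is.numeric(th) || th <= 0 || th >= 1)
    errors <- c(errors, "cluster$threshold must lie in (0, 1)")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    errors <- c(errors, sprintf("input FASTA not found: %s", cfg$input))
  if (!is.null(cfg$dateOnly) && !file.exists(cfg$dateOnly))
    errors <- c(errors, sprintf("dateOnly TSV not found: %s", cfg$dateOnly))
  if (is.null(cfg$input) && is.null(cfg$simulate) && is.null(cfg$dateOnly))
    errors <- c(errors, "one of 'input', 'simulate' or 'dateOnly' is required")
  list(config = cfg, errors = errors, warnings = warnings)
}

.sigfig <- function(x, digits) ifelse(is.na(x), NA_real_, signif(x, digits))

#' Tabulate provirus calls as a per-call report
#'
#' One row per call: coordinates and length of both LTRs, alignment
#' identity, K2P divergence with SE and difference counts, age at every
#' rate of each call's panel, hallmark-motif flags, ORF order, defect
#' counts, and TSD evidence. Ages are reported at \code{agesDigits}
#' significant figures and are recomputed from the printed divergence so
#' that re-dating the report's D column reproduces its age columns exactly.
#'
#' @param calls list of \linkS4class{ProvirusCall}.
#' @param panel rate panel (labels become age column suffixes).
#' @param agesDigits significant figures for ages.
#' @param distDigits decimals for distances.
#' @return data.frame, one row per call.
#' @export
provirusReport <- function(calls, panel = defaultRatePanel(), agesDigits = 3L,
                           distDigits = 3L) {
  rows <- lapply(calls, function(call) {
    p <- call@ltrPair
    d <- call@divergence
    Dprint <- round(d@value, distDigits)
    ages <- dateWithRatePanel(Dprint, panel, d@se)
    ageCols <- setNames(as.list(.sigfig(ages$T_MY, agesDigits)),
                        paste0("T_MY_", panel$label))
    mot <- call@ltrPair@motifs
    rep0 <- call@intactness
    cbind(data.frame(
      contig = p@contig, strand = p@strand,
      ltr5_start = start(p@left), ltr5_end = end(p@left),
      ltr3_start = start(p@right), ltr3_end = end(p@right),
      ltr_length = as.integer(round((width(p@left) + width(p@right)) / 2)),
      identity = round(p@identity, 4),
      D = Dprint, D_se = round(d@se, distDigits + 2L),
      n_diff = d@nDiff, n_sites = d@nSites),
      as.data.frame(ageCols),
      data.frame(
        starts_TG = mot$left$startsTG && mot$right$startsTG,
        ends_CA = mot$left$endsCA && mot$right$endsCA,
        polyA = !is.na(mot$left$polyA) || !is.na(mot$right$polyA),
        at_rich = !is.na(mot$left$atRich) || !is.na(mot$right$atRich),
        orf_order_ok = call@orfOrderOk,
        n_orfs = length(call@orfs),
        n_nonsense = if (is.null(rep0)) NA_integer_ else rep0@nNonsense,
        n_frameshift = if (is.null(rep0)) NA_integer_ else rep0@nFrameshift,
        tsd_length = if (length(call@tsd)) width(call@tsd)[1] else 0L,
        flags = paste(p@flags, collapse = ";")))
  })
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Stages, in order, as configured: simulate (a parameter grid becomes
#' contigs + a truth table), scan (LTR pairs to provirus calls, dated and
#' defect-scored), cluster (pairwise distances of internal regions,
#' neighbor-joining tree, threshold lineages), with per-stage outputs under
#' \code{outDir}: \code{report.tsv}, \code{calls.gff3}, \code{tree.nwk},
#' \code{lineages.tsv}, \code{summary.json}, \code{resolved_config.json} and
#' \code{run.log}. In \code{dateOnly} mode a TSV with a \code{D} column is
#' re-dated under the rate panel and written as \code{dates.tsv}. Any stage
#' failure halts the run with a stage-attributed error. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config configuration list, see \code{\link{validateConfig}}.
#' @return invisibly, a list with the calls, the report data.frame, the
#'   lineage partition (or NULL) and the output paths.
#' @export
runPipeline <- function(config = list()) {
  v <- validateConfig(config)
  for (w in v$warnings) warning(w, call. = FALSE)
  if (length(v$errors))
    .ervStop(paste("invalid configuration:", paste(v$errors, collapse = "; ")),
             "configError")
  cfg <- v$config
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  note <- function(stage, msg) {
    logLines <<- c(logLines, sprintf("[%s] %s", stage, msg))
  }
  fail <- function(stage, e)
    .ervStop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             "stageError")
  outfile <- function(f) file.path(cfg$outDir, f)
  echo <- cfg[!vapply(cfg, is.null, logical(1))]
  echo$outDir <- NULL                    # machine-specific, not part of the run
  jsonlite::write_json(echo, outfile("resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  note("config", sprintf("seed %d; rates %s", as.integer(cfg$seed),
                         paste(cfg$ratePanel$rate, collapse = "/")))

  if (!is.null(cfg$dateOnly)) {
    tab <- tryCatch(read.delim(cfg$dateOnly), error = function(e)
      fail("date", e))
    if (!"D" %in% names(tab))
      fail("date", simpleError("dateOnly TSV must have a 'D' column"))
    dated <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      ages <- dateWithRatePanel(tab$D[i], cfg$ratePanel)
      setNames(data.frame(t(.sigfig(ages$T_MY, cfg$precision$ages))),
               paste0("T_MY_", cfg$ratePanel$label))
    }))
    dated <- cbind(tab, dated)
    write.table(dated, outfile("dates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("date", sprintf("dated %d divergence value(s)", nrow(dated)))
    writeLines(logLines, outfile("run.log"))
    return(invisible(list(dates = dated, files = outfile("dates.tsv"))))
  }

  seqs <- NULL
  truth <- NULL
  sims <- NULL
  if (!is.null(cfg$simulate)) {
    ds <- tryCatch(
      generateDataset(cfg$simulate, seed = cfg$seed,
                      fastaPath = outfile("simulated.fa"),
                      truthPath = outfile("truth.tsv")),
      ervclockError = function(e) fail("simulate", e),
      error = function(e) fail("simulate", e))
    seqs <- ds$sequences
    truth <- ds$truth
    sims <- ds$simulations
    note("simulate", sprintf("%d contig(s) generated", length(seqs)))
  }
  if (!is.null(cfg$input)) {
    inSeqs <- tryCatch(readFasta(cfg$input), error = function(e)
      fail("read", e))
    seqs <- if (is.null(seqs)) inSeqs else c(seqs, inSeqs)
    note("read", sprintf("%d contig(s) read from %s", length(inSeqs), cfg$input))
  }

  scanCfg <- do.call(ltrScanConfig, cfg$scan)
  userPol <- NULL
  if (!is.null(cfg$polReference)) {
    userPol <- if (file.exists(cfg$polReference))
      as.character(readBStringSet(cfg$polReference))[[1]]
    else cfg$polReference
  }
  simPol <- if (!is.null(sims))
    setNames(lapply(sims, function(s) as.character(polReference(s))),
             vapply(sims, function(s) names(contigSeq(s)), character(1)))
  else list()

  calls <- list()
  for (i in seq_along(seqs)) {
    cid <- names(seqs)[i]
    ref <- if (!is.null(userPol)) userPol else simPol[[cid]]
    pairs <- tryCatch(findLTRPairs(seqs[i], scanCfg), error = function(e)
      fail("scan", e))
    note("scan", sprintf("%s: %d candidate pair(s)", cid, length(pairs)))
    for (pair in pairs) {
      call <- tryCatch(
        callProvirus(seqs[i], pair, ref, scanCfg, cfg$ratePanel),
        ervclockError = function(e) {
          note("scan", sprintf("%s: candidate rejected (%s)", cid,
                               conditionMessage(e)))
          NULL
        })
      if (!is.null(call)) calls[[length(calls) + 1L]] <- call
    }
  }
  report <- provirusReport(calls, cfg$ratePanel, cfg$precision$ages,
                           cfg$precision$dist)
  write.table(report, outfile("report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeGFF3(calls, setNames(width(seqs), names(seqs)), outfile("calls.gff3"))
  note("report", sprintf("%d provirus call(s) reported", length(calls)))

  part <- NULL
  if (length(calls) >= 3L) {
    intSeqs <- setNames(vapply(calls, function(call) {
      substr(as.character(seqs[[call@ltrPair@contig]]),
             start(call@internal), end(call@internal))
    }, character(1)), make.unique(vapply(calls, function(call)
      call@ltrPair@contig, character(1))))
    clustered <- tryCatch({
      dm <- distanceMatrix(DNAStringSet(intSeqs), model = cfg$cluster$model)
      part <- cutLineages(dm, cfg$cluster$threshold)
      tree <- neighborJoining(dm)
      ape::write.tree(tree, outfile("tree.nwk"))
      write.table(data.frame(id = names(membership(part)),
                             lineage = membership(part)),
                  outfile("lineages.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    }, ervclockError = function(e) {
      note("cluster", sprintf("skipped: %s", conditionMessage(e)))
      FALSE
    })
    if (clustered)
      note("cluster", sprintf("%d lineage(s) at threshold %.2f",
                              length(unique(membership(part))),
                              cfg$cluster$threshold))
  }

  summaryList <- list(
    n_contigs = length(seqs),
    n_calls = length(calls),
    mean_D = if (length(calls)) mean(vapply(calls, function(x)
      x@divergence@value, numeric(1))) else NA,
    n_lineages = if (!is.null(part)) length(unique(membership(part))) else NA,
    seed = as.integer(cfg$seed))
  jsonlite::write_json(summaryList, outfile("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(logLines, outfile("run.log"))
  invisible(list(calls = calls, report = report, lineages = part,
                 truth = truth, outDir = cfg$outDir))
}
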