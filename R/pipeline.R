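# Orchestration: simulate -> detect -> analyze -> report.

#' Analyze one experiment
#'
#' Runs the full analysis chain on a \linkS4class{CalciumExperiment}:
#' event detection, spontaneous/evoked classification, onset latencies,
#' spontaneous-peak normalization, probability coding, latency statistics,
#' synchrony and size/non-CF analyses.
#'
#' @param x a \linkS4class{CalciumExperiment} with \code{"dff"} (or
#'   \code{"F"}, see \code{fromRaw}) and a protocol in its metadata.
#' @param expId experiment identifier attached to all tables.
#' @param fromRaw recompute dF/F from the raw \code{"F"} assay with
#'   [computeDff()] before detection.
#' @param seed RNG seed for the randomized non-CF integration windows.
#' @return named list of tables (data.frames) plus the classified
#'   \code{events} table.
#' @export
analyzeExperiment <- function(x, expId = 1L, fromRaw = FALSE, seed = 1) {
  if (fromRaw || !"dff" %in% names(assays(x))) x <- computeDff(x)
  prot <- protocol(x)
  if (is.null(prot)) stop("experiment carries no stimulus protocol")
  durS <- ncol(x) * samplePeriod(x) / 1000

  events <- detectEvents(x)
  events <- classifyEvents(events, prot)
  events <- estimateLatencies(x, events)
  nDen <- nrow(x)

  tabs <- list()
  tabs$spont_rate <- cbind(experiment = expId,
                           spontaneousRate(events, durS, prot, nDen))
  tabs$probability <- cbind(experiment = expId,
                            eventProbability(events, prot, nDen))

  # per-dendrite categorization (duration data only)
  if (prot@mode == "duration") {
    pm <- probabilityMatrix(tabs$probability)
    conds <- intersect(.conditionLevels("duration"), colnames(pm))
    nTr <- sum(prot@trials$condition == conds[1])
    cats <- lapply(seq_len(nDen), function(d)
      categorizeDendrite(pm[d, conds], sp = pm[d, "sp"], nTrials = nTr))
    tabs$categories <- data.frame(
      experiment = expId, dendrite_id = seq_len(nDen),
      category = vapply(cats, `[[`, integer(1), "category"),
      threshold = vapply(cats, `[[`, integer(1), "threshold"),
      unresponsive = vapply(cats, `[[`, logical(1), "unresponsive"))
  }

  ls <- latencyStats(events)
  if (nrow(ls$perDendrite))
    tabs$latency <- cbind(experiment = expId, ls$perDendrite)
  lw <- latencyWindowCounts(events)
  if (nrow(lw)) tabs$latency_windows <- cbind(experiment = expId, lw)

  exclusionLog <- character(0)
  co <- tryCatch(coactivationFraction(events, prot), error = function(e) e)
  if (inherits(co, "error")) {
    exclusionLog <- c(exclusionLog, paste0("experiment ", expId, ": ",
                                           conditionMessage(co)))
    responsive <- responsiveDendrites(events, prot, nDen)
  } else {
    tabs$coactivation <- cbind(experiment = expId, co$perTrial)
    responsive <- co$responsive
  }
  if (length(responsive) >= 2L) {
    pj <- pairJointProbability(events, prot, responsive)
    tabs$pair_joint <- cbind(experiment = expId, pj)
  }

  # sizes, sp reference, enhancement, non-CF -------------------------------
  x <- normalizeExperiment(x, events)
  sz <- eventSizes(x, events)
  events <- sz$events
  excl <- excludeMultiEventTrials(events)
  tabs$exclusion <- data.frame(experiment = expId,
                               multi_event_fraction = excl$fraction)
  usable <- events[excl$keep, , drop = FALSE]
  sizeRows <- usable[is.finite(usable$norm_integral), , drop = FALSE]
  tabs$event_sizes <- data.frame(
    experiment = expId, dendrite_id = sizeRows$dendrite_id,
    condition = ifelse(sizeRows$label == "evoked", sizeRows$condition, "sp"),
    norm_integral = sizeRows$norm_integral, stringsAsFactors = FALSE)

  amp <- .amplitudeAnalysis(x, usable, sz$spontMean, seed = seed)
  if (nrow(amp$enhancement))
    tabs$enhancement <- cbind(experiment = expId, amp$enhancement)
  if (nrow(amp$noncf))
    tabs$noncf <- cbind(experiment = expId, amp$noncf)

  # distance dependence of spontaneous co-activation (with shuffle control)
  if (nDen >= 2L) {
    sc <- tryCatch(
      spontDistanceCorrelation(events, rowData(x)$position_um, durS,
                               framePeriodMs = framePeriod(x),
                               protocol = prot, nShuffles = 20, seed = seed),
      error = function(e) NULL)
    if (!is.null(sc))
      tabs$spont_distance <- cbind(experiment = expId, sc$byDistance)
  }

  if (all(c("ipsi", "contra") %in% prot@trials$laterality))
    tabs$laterality <- cbind(experiment = expId,
                             classifyLaterality(events, prot, nDen))

  list(tables = tabs, events = events, exclusionLog = exclusionLog)
}

# evoked mean traces, jitter-matched sp reference, enhancement integrals
# and non-CF extraction for one experiment
.amplitudeAnalysis <- function(x, events, spontMean, seed = 1,
                               windowMs = c(-200, 800)) {
  ndff <- assay(x, "ndff")
  sp <- samplePeriod(x)
  tr <- protocol(x)@trials
  conds <- intersect(.allConditionLevels(), unique(tr$condition))
  enh <- list()
  rand <- .withSeed(seed * 701L + 23L,
                    matrix(stats::runif(nrow(ndff) * length(conds),
                                        EVOKED_WINDOW_MS[1],
                                        EVOKED_WINDOW_MS[2]),
                           nrow(ndff), length(conds)))
  for (d in seq_len(nrow(ndff))) {
    spEv <- events[events$dendrite_id == d & events$label == "spontaneous", ]
    if (!nrow(spEv)) next
    nz <- normalizeToSpontaneous(assay(x, "dff")[d, ], spEv$peak_index, sp)
    # The reference event shape is the CF kernel scaled to the dendrite's
    # mean spontaneous event by least squares over the clean part of its
    # decay ([+20, +300] ms after the peak). The raw aligned average is
    # unsuitable as a substitution shape: it carries the refractory hole
    # and post-refractory intensity bump of the surrounding activity, a
    # noise-selection spike at the alignment sample, and conditional
    # suppression of its flanks. The kernel keeps the trace's normalized
    # scale, so at gain 1 the substituted events cancel the evoked events
    # exactly, irrespective of the baseline convention inside the
    # normalization divisor.
    me <- nz$meanEvent
    po <- nz$peakOffset
    cfgK <- metadata(x)$config
    kp <- if (!is.null(cfgK))
      cfKernelParams(cfgK@kernelRise, cfgK@kernelDecayHalf)
    else cfKernelParams()
    rel <- (seq_along(me) - po) * sp
    kern <- cfKernel(rel + kp$peakT, kp)
    # fit inside the refractory-protected part of the decay, where the
    # surrounding-activity background is at its local level rather than
    # the recovered pedestal
    fitIdx <- which(rel >= 20 & rel <= 150 & is.finite(me))
    a <- sum(me[fitIdx] * kern[fitIdx]) / sum(kern[fitIdx]^2)
    shape <- a * kern
    pm <- peristimulusMatrix(ndff[d, ], sp, tr$onset_s * 1000, windowMs)
    tms <- attr(pm, "time_ms")
    preIdx <- tms >= -150 & tms < 0
    # condition the background like the non-CF extraction does: drop
    # trials with any other detected event from -450 ms up to the evoked
    # window or in the 100 ms the integration window reaches beyond it,
    # so baseline and analysis window see the same (event-free) background
    # in both routes
    pkAll <- events$peak_time_ms[events$dendrite_id == d]
    onsAll <- tr$onset_s * 1000
    dirty <- tr$trial_id[vapply(onsAll, function(o)
      any((pkAll >= o - 450 & pkAll < o + EVOKED_WINDOW_MS[1]) |
            (pkAll >= o + EVOKED_WINDOW_MS[2] &
               pkAll < o + EVOKED_WINDOW_MS[2] + 100)), logical(1))]
    for (ci in seq_along(conds)) {
      cc <- conds[ci]
      evd <- events[events$dendrite_id == d & events$label == "evoked" &
                      events$condition == cc &
                      !(events$trial_id %in% dirty), , drop = FALSE]
      if (!nrow(evd)) next
      rows <- match(evd$trial_id, tr$trial_id)
      sub <- pm[rows, , drop = FALSE]
      sub <- sub - rowMeans(sub[, preIdx, drop = FALSE], na.rm = TRUE)
      evokedMean <- structure(colMeans(sub, na.rm = TRUE), time_ms = tms)
      # place the substituted events at onset + rise rather than at the
      # detected argmax sample, whose noise bias sits a few ms late on the
      # flat transient top; the 10%-crossing onset estimate is unbiased
      peaksRel <- evd$peak_time_ms - tr$onset_s[rows] * 1000
      if (!is.null(evd$onset_latency_ms)) {
        ok <- is.finite(evd$onset_latency_ms)
        peaksRel[ok] <- evd$onset_latency_ms[ok] + kp$peakT
      }
      spRef <- buildSpReference(shape, po, peaksRel, sp, windowMs)
      et <- enhancementTrace(evokedMean, spRef)
      t0 <- rand[d, ci]
      i0 <- which.min(abs(tms - t0))
      integral <- eventIntegral(as.numeric(et), sp, i0) / spontMean[d]
      enh[[length(enh) + 1L]] <- data.frame(
        dendrite_id = d, condition = cc, n_events = nrow(evd),
        integral = integral, sp_ref_peak = max(spRef),
        stringsAsFactors = FALSE)
    }
  }
  ncf <- extractNonCF(x, events, spontMean, seed = seed, windowMs = windowMs)
  list(enhancement = if (length(enh)) do.call(rbind, enh) else data.frame(),
       noncf = if (nrow(ncf$stats)) ncf$stats else data.frame(),
       noncfTraces = ncf$traces)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates \code{config@nExperiments} experiments (each with its own
#' derived seed), analyzes each, aggregates the per-figure tables, applies
#' the statistical tests and returns an \linkS4class{AnalysisReport}.
#' Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param mode \code{"duration"} or \code{"pressure"}.
#' @param lateralities stimulated sides (see [makeProtocol()]).
#' @param outdir optional directory; when given, tables are written as CSV
#'   via [writeReport()].
#' @param fromRaw recompute dF/F from raw fluorescence in each experiment.
#' @return an \linkS4class{AnalysisReport}.
#' @export
runPipeline <- function(config, mode = "duration", lateralities = "ipsi",
                        outdir = NULL, fromRaw = FALSE) {
  allTabs <- list()
  exclusionLog <- character(0)
  for (e in seq_len(config@nExperiments)) {
    seedE <- config@seed + 1000L * e
    x <- simulateExperiment(config, mode, lateralities, seed = seedE)
    res <- analyzeExperiment(x, expId = e, fromRaw = fromRaw, seed = seedE)
    exclusionLog <- c(exclusionLog, res$exclusionLog)
    for (nm in names(res$tables))
      allTabs[[nm]] <- rbind(allTabs[[nm]], res$tables[[nm]])
  }
  # pooled extra synchrony across all pairs
  if (!is.null(allTabs$pair_joint))
    allTabs$extra_synchrony <- extraSynchrony(allTabs$pair_joint)
  if (!is.null(allTabs$enhancement) && !is.null(allTabs$noncf)) {
    enh <- allTabs$enhancement
    ncf <- allTabs$noncf
    enh$dendrite_id <- paste(enh$experiment, enh$dendrite_id)
    ncf$dendrite_id <- paste(ncf$experiment, ncf$dendrite_id)
    allTabs$linearity <- linearityComparison(
      enh[, c("dendrite_id", "condition", "integral")],
      data.frame(dendrite_id = ncf$dendrite_id, condition = ncf$condition,
                 integral = ncf$integral))
  }
  tests <- statTests(allTabs)
  report <- new("AnalysisReport", tables = allTabs, tests = tests,
                runMetadata = list(
                  seed = config@seed, mode = mode,
                  n_experiments = config@nExperiments,
                  exclusion_log = exclusionLog,
                  r_version = as.character(getRversion()),
                  package_version = as.character(
                    utils::packageVersion("cfcalcium"))))
  if (!is.null(outdir)) writeReport(report, outdir)
  report
}

#' Statistical tests on the aggregated tables
#'
#' Two-way ANOVA (factors: condition and experiment) with Tukey HSD
#' post-hoc on the probability, latency, coactivation, extra-synchrony and
#' size tables; two-sample Kolmogorov-Smirnov tests on the latency-window
#' counts of the weakest vs strongest condition; a two-sample t test of
#' measured vs independent joint probabilities per condition. All tests are
#' two-tailed; p-values are reported exactly.
#'
#' @param tables named list of report tables.
#' @return data.frame with \code{name}, \code{statistic}, \code{df},
#'   \code{p}, \code{note}.
#' @export
statTests <- function(tables) {
  out <- list()
  add <- function(name, statistic, df, p, note = "") {
    out[[length(out) + 1L]] <<- data.frame(
      name = name, statistic = statistic, df = df, p = p, note = note,
      stringsAsFactors = FALSE)
  }
  aovTest <- function(df, value, name) {
    df <- df[is.finite(df[[value]]), , drop = FALSE]
    if (is.null(df) || !nrow(df) || length(unique(df$condition)) < 2L) {
      add(name, NA_real_, NA_real_, NA_real_, "skipped: <2 condition groups")
      return(invisible(NULL))
    }
    df$condition <- factor(df$condition)
    df$experiment <- factor(df$experiment)
    form <- if (nlevels(df$experiment) > 1L)
      stats::as.formula(paste(value, "~ condition + experiment"))
    else stats::as.formula(paste(value, "~ condition"))
    fit <- stats::aov(form, data = df)
    s <- summary(fit)[[1]]
    i <- match("condition", trimws(rownames(s)))
    add(name, s[i, "F value"], s[i, "Df"], s[i, "Pr(>F)"])
    tk <- stats::TukeyHSD(fit, "condition")$condition
    for (r in rownames(tk))
      add(paste0(name, "_tukey_", r), tk[r, "diff"], NA_real_,
          tk[r, "p adj"])
  }

  if (!is.null(tables$probability)) {
    pr <- tables$probability
    aovTest(pr[pr$condition != "sp", ], "prob", "probability_anova")
  }
  if (!is.null(tables$latency)) {
    aovTest(tables$latency, "median_ms", "latency_median_anova")
    aovTest(tables$latency, "mad_ms", "latency_mad_anova")
  }
  if (!is.null(tables$coactivation))
    aovTest(tables$coactivation, "fraction", "coactivation_anova")
  if (!is.null(tables$pair_joint)) {
    pj <- tables$pair_joint
    pj$extra_pct <- 100 * (pj$measured - pj$independent)
    aovTest(pj[pj$condition != "sp", ], "extra_pct", "extra_synchrony_anova")
    for (cc in setdiff(unique(pj$condition), "sp")) {
      g <- pj[pj$condition == cc, ]
      if (nrow(g) >= 2L) {
        tt <- stats::t.test(g$measured, g$independent)
        add(paste0("joint_prob_t_", cc), unname(tt$statistic),
            unname(tt$parameter), tt$p.value)
      }
    }
  }
  if (!is.null(tables$event_sizes)) {
    es <- tables$event_sizes
    es <- es[es$condition != "sp", , drop = FALSE]
    # per-dendrite means to avoid pseudo-replication across events
    agg <- stats::aggregate(norm_integral ~ experiment + dendrite_id + condition,
                            es, mean)
    aovTest(agg, "norm_integral", "event_size_anova")
  }
  if (!is.null(tables$noncf))
    aovTest(tables$noncf, "rise_ms", "noncf_rise_anova")
  if (!is.null(tables$latency_windows)) {
    lw <- tables$latency_windows
    conds <- intersect(.allConditionLevels(), unique(lw$condition))
    if (length(conds) >= 2L) {
      weak <- conds[1]; strong <- conds[length(conds)]
      for (w in unique(lw$window)) {
        a <- lw$count[lw$condition == weak & lw$window == w]
        b <- lw$count[lw$condition == strong & lw$window == w]
        if (length(a) >= 2L && length(b) >= 2L) {
          ks <- suppressWarnings(stats::ks.test(a, b))
          add(paste0("latency_window_ks_", w, "_", weak, "_vs_", strong),
              unname(ks$statistic), NA_real_, ks$p.value)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(name = character(0), statistic = numeric(0), df = numeric(0),
               p = numeric(0), note = character(0))
}

#' Write an AnalysisReport to CSV files
#'
#' One CSV per table plus \code{tests.csv} and \code{metadata.json};
#' numbers are written in full precision so identical runs produce
#' byte-identical files.
#'
#' @param report an \linkS4class{AnalysisReport}.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
writeReport <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report@tables)) {
    df <- report@tables[[nm]]
    for (cl in names(df)) if (is.numeric(df[[cl]]))
      df[[cl]] <- sprintf("%.12g", df[[cl]])
    utils::write.csv(df, file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  tests <- report@tests
  for (cl in names(tests)) if (is.numeric(tests[[cl]]))
    tests[[cl]] <- sprintf("%.12g", tests[[cl]])
  utils::write.csv(tests, file.path(outdir, "tests.csv"), row.names = FALSE)
  md <- report@runMetadata
  jsonlite::write_json(md, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
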