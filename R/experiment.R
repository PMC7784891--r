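# Full virtual experiment: generate every condition, run every analysis,
# aggregate per-animal / per-channel, and check condition-contrast signs.

#' Configure a virtual experiment
#'
#' @param presets condition labels (see [presetLabels()]).
#' @param nAnimals animals per condition (default 5).
#' @param channelsPerAnimal LFP channels per animal (default 3, i.e. 15
#'   channels over 5 animals per condition).
#' @param nTrials click trains per channel (default 50).
#' @param seed master seed; all per-stage seeds are derived from it and
#'   recorded in the run summary.
#' @param band analysis band (Hz), default c(35, 44).
#' @param spikeDuration,ipscDuration session lengths (s) for the spike and
#'   sIPSC recordings.
#' @param ymazeEntries arm entries per Y-maze session.
#' @param nShuffles shuffle count for the spike null (0 disables).
#' @return a list of class \code{"gsExperimentConfig"}.
#' @export
experimentConfig <- function(presets = c("control", "mutant",
                                         "mutant_gsk3b_inhibited",
                                         "mutant_gsk3b_knockdown"),
                             nAnimals = 5, channelsPerAnimal = 3,
                             nTrials = 50, seed = 1, band = c(35, 44),
                             spikeDuration = 300, ipscDuration = 300,
                             ymazeEntries = 30, nShuffles = 0) {
  stopifnot(nAnimals >= 1, channelsPerAnimal >= 1, nTrials >= 1)
  bad <- setdiff(presets, presetLabels())
  if (length(bad)) stop("unknown preset label(s): ", paste(bad, collapse = ", "))
  structure(list(presets = presets, nAnimals = nAnimals,
                 channelsPerAnimal = channelsPerAnimal, nTrials = nTrials,
                 seed = seed, band = band, spikeDuration = spikeDuration,
                 ipscDuration = ipscDuration, ymazeEntries = ymazeEntries,
                 nShuffles = nShuffles),
            class = "gsExperimentConfig")
}

# expected direction of each mutant-vs-control contrast
.contrastDirections <- c(evoked = -1, baseline = 1, itc = -1, n1 = -1,
                         spike_r = -1, ipsc_pct = -1, alternation = -1,
                         ppi = -1)

#' Run a virtual experiment
#'
#' For every condition preset, simulates the full recording battery
#' (per-channel ASSR LFP sessions; one spike pair, one sIPSC pair, one
#' Y-maze and one startle session per animal), runs every analysis, and
#' assembles a long-format metric table.  Metrics per channel: evoked,
#' total and baseline band power, ITC band metric, N1 amplitude.  Metrics
#' per animal: spike-pair zero-lag r, synchronous sIPSC percentage, mean
#' sIPSC inter-event interval (ms), alternation index, mean \%PPI.
#'
#' The condition-contrast summary reports, for each headline metric, the
#' per-animal group means, whether the mutant-vs-control difference has
#' the phenotype direction (evoked, ITC, N1, spike r, sIPSC \%,
#' alternation and PPI lower in the mutant; baseline power higher), and
#' whether each treated preset is restored (closer to control than to
#' mutant) -- the N1 is expected NOT to restore.
#'
#' Fully reproducible: all randomness derives from \code{config$seed}.
#'
#' @param config a config from [experimentConfig()].
#' @param outDir optional directory; if given, writes
#'   \code{metrics_per_channel.csv}, \code{metrics_per_animal.csv} and
#'   \code{summary.json} there.
#' @return list with \code{metrics} (per-channel long table),
#'   \code{perAnimal} (aggregated), \code{contrasts} (per-metric summary
#'   data.frame), \code{groupMeans}, and \code{config}.
#' @export
runExperiment <- function(config = experimentConfig(), outDir = NULL) {
  stopifnot(inherits(config, "gsExperimentConfig"))
  nStreams <- length(config$presets) * config$nAnimals *
    (config$channelsPerAnimal + 8)
  seeds <- deriveSeeds(config$seed, nStreams)
  sIdx <- 0L
  nextSeed <- function() {
    sIdx <<- sIdx + 1L
    seeds[sIdx]
  }
  rows <- list()
  addRow <- function(subject, channel, condition, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject, channel = channel, condition = condition,
      metric = metric, value = value, stringsAsFactors = FALSE)

  for (lbl in config$presets) {
    preset <- makePreset(lbl)
    for (a in seq_len(config$nAnimals)) {
      subj <- sprintf("%s_m%d", lbl, a)
      for (ch in seq_len(config$channelsPerAnimal)) {
        chId <- sprintf("ch%d", ch)
        x <- generateAssrTrials(preset, nTrials = config$nTrials,
                                seed = nextSeed(), subjectId = subj,
                                channelId = chId)
        xz <- zscoreLfp(x)
        addRow(subj, chId, lbl, "evoked",
               assrPower(xz, "evoked", band = config$band)$value)
        addRow(subj, chId, lbl, "total",
               assrPower(xz, "total", band = config$band)$value)
        addRow(subj, chId, lbl, "baseline",
               baselinePower(xz, band = config$band)$value)
        addRow(subj, chId, lbl, "itc",
               intertrialCoherence(xz, band = config$band)@bandMetric)
        addRow(subj, chId, lbl, "n1", n1Amplitude(xz)$amplitude)
      }
      sp <- generateSpikePair(preset@spikeRate, preset@spikeSharedFrac,
                              config$spikeDuration, seed = nextSeed())
      cc <- if (config$nShuffles >= 20)
        shuffleNull(sp, config$nShuffles, seed = nextSeed())
      else {
        nextSeed()   # keep the seed stream aligned across configs
        crossCorrelation(sp)
      }
      addRow(subj, "pair", lbl, "spike_r", cc@coefficient)
      tr <- generateEventTrainPair(preset@ipscIndepRate,
                                   preset@ipscSharedRate,
                                   config$ipscDuration, seed = nextSeed())
      sync <- synchronousFraction(tr)
      addRow(subj, "pair", lbl, "ipsc_pct", sync@pctSynchronous)
      addRow(subj, "pair", lbl, "ipsc_iei_ms",
             1000 * interEventIntervals(tr)$grandMean)
      ym <- generateYmazeSession("lapse", config$ymazeEntries,
                                 seed = nextSeed(),
                                 lapseProb = preset@alternationLapse)
      addRow(subj, "session", lbl, "alternation", alternationIndex(ym))
      pp <- generatePpiSession(preset, seed = nextSeed())
      addRow(subj, "session", lbl, "ppi", mean(ppiPercent(pp)$ppi))
      nextSeed(); nextSeed(); nextSeed()   # reserved streams
    }
  }
  metrics <- do.call(rbind, rows)
  perAnimal <- aggregateMetrics(metrics, "per_animal")

  gm <- stats::aggregate(value ~ condition + metric, data = perAnimal,
                         FUN = mean)
  groupMean <- function(cond, met) {
    v <- gm$value[gm$condition == cond & gm$metric == met]
    if (length(v)) v else NA_real_
  }
  contrasts <- NULL
  if (all(c("control", "mutant") %in% config$presets)) {
    treated <- setdiff(config$presets, c("control", "mutant"))
    contrasts <- do.call(rbind, lapply(names(.contrastDirections), function(met) {
      ctrl <- groupMean("control", met)
      mut <- groupMean("mutant", met)
      row <- data.frame(metric = met, control = ctrl, mutant = mut,
                        expectedDirection = .contrastDirections[[met]],
                        signOk = sign(mut - ctrl) == .contrastDirections[[met]],
                        stringsAsFactors = FALSE)
      for (tl in treated) {
        tv <- groupMean(tl, met)
        row[[tl]] <- tv
        row[[paste0(tl, "_restored")]] <- abs(tv - ctrl) < abs(tv - mut)
      }
      row
    }))
  }
  result <- list(metrics = metrics, perAnimal = perAnimal,
                 contrasts = contrasts, groupMeans = gm, config = config,
                 seeds = seeds)
  if (!is.null(outDir)) writeExperiment(result, outDir)
  result
}

#' Write the outputs of [runExperiment()] to a directory
#'
#' @param result the list returned by [runExperiment()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeExperiment <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pChan <- file.path(outDir, "metrics_per_channel.csv")
  pAnim <- file.path(outDir, "metrics_per_animal.csv")
  pJson <- file.path(outDir, "summary.json")
  utils::write.csv(result$metrics, pChan, row.names = FALSE)
  utils::write.csv(result$perAnimal, pAnim, row.names = FALSE)
  summary <- list(
    config = unclass(result$config),
    groupMeans = result$groupMeans,
    contrasts = result$contrasts,
    allSignsOk = if (is.null(result$contrasts)) NA else
      all(result$contrasts$signOk)
  )
  jsonlite::write_json(summary, pJson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(pChan, pAnim, pJson))
}
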