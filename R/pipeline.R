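#' @include AllClasses.R
NULL

.COG_MEASURES <- c(
  "global", "processing_speed", "attention", "executive_function", "smmse"
)

.COVARIATE_SETS <- c(
  "base", "+smmse", "+gds", "+bmi", "+whr", "+interval", "gmv-swap"
)

# covariate lists for the two model groups under a validation selector:
# behavioural models (handgrip -> cognition) omit head-size covariates;
# FC models add intracranial volume (or grey-matter volume under the swap)
.covariateLists <- function(covariateSet = "base") {
  covariateSet <- match.arg(covariateSet, .COVARIATE_SETS)
  behav <- c("age", "sex", "education")
  fcVol <- "ticv"
  extra <- switch(covariateSet,
    "base" = character(),
    "+smmse" = "smmse",
    "+gds" = "gds",
    "+bmi" = "bmi",
    "+whr" = "whr",
    "+interval" = "scan_interval",
    "gmv-swap" = character()
  )
  if (covariateSet == "gmv-swap") fcVol <- "gmv"
  list(
    behavioural = c(behav, extra),
    fc = c(behav, fcVol, extra)
  )
}

#' Run the standard association families of the analysis
#'
#' Given a merged subject table (scored phenotypes + segregation profile
#' columns), fits the five association families of the design, each with
#' Benjamini-Hochberg correction within the family:
#' \describe{
#'   \item{cognition}{handgrip -> the five cognitive measures (global,
#'     processing speed, attention, executive function, SM-MMSE);
#'     covariates age, sex, education.}
#'   \item{segregation}{handgrip -> the nine network-level segregation
#'     measures (corrected) plus global segregation (reported alongside,
#'     excluded from the correction); covariates add intracranial
#'     volume.}
#'   \item{focal_fc}{handgrip -> the focal network's intra-network mean
#'     FC and its eight inter-network mean FCs (nine measures).}
#'   \item{focal_edges}{handgrip -> every region-pair edge within the
#'     focal network (231 for a 22-region network).}
#'   \item{fc_cognition}{each focal FC measure (network segregation,
#'     intra-network FC, and any edge significant in `focal_edges`) ->
#'     the five cognitive measures, corrected per FC measure.}
#' }
#' Validation selectors add one covariate to every model or swap
#' intracranial for grey-matter volume; they never change the family
#' structure.
#'
#' @param data merged data.frame (one row per subject) containing
#'   `handgrip`, the cognitive measures, covariates and the
#'   `seg_global` / `seg.*` / `intra.*` / `inter.*` / `edge.*` columns
#'   from [profileTable()].
#' @param focal focal network label
#'   (default `"salience_ventral_attention"`).
#' @param nets network labels (default [networkLabels()]).
#' @param covariateSet one of `"base"`, `"+smmse"`, `"+gds"`, `"+bmi"`,
#'   `"+whr"`, `"+interval"`, `"gmv-swap"`.
#' @param alpha FDR significance level, default 0.05.
#' @return Named list of data.frames, one per family.
#' @export
runStandardFamilies <- function(data, focal = "salience_ventral_attention",
                                nets = networkLabels(),
                                covariateSet = "base", alpha = 0.05) {
  cl <- .covariateLists(covariateSet)
  segCols <- paste0("seg.", nets)
  interCols <- grep("^inter\\.", names(data), value = TRUE)
  interCols <- interCols[
    vapply(strsplit(interCols, ".", fixed = TRUE),
      function(p) focal %in% p, logical(1))
  ]
  edgeCols <- grep("^edge\\.", names(data), value = TRUE)

  out <- list()
  out$cognition <- runFamily(
    data, .COG_MEASURES, "handgrip", cl$behavioural,
    family = "cognition", alpha = alpha
  )
  out$segregation <- runFamily(
    data, c("seg_global", segCols), "handgrip", cl$fc,
    family = "segregation", correct = segCols, alpha = alpha
  )
  out$focal_fc <- runFamily(
    data, c(paste0("intra.", focal), interCols), "handgrip", cl$fc,
    family = "focal_fc", alpha = alpha
  )
  if (length(edgeCols)) {
    out$focal_edges <- runFamily(
      data, edgeCols, "handgrip", cl$fc,
      family = "focal_edges", alpha = alpha
    )
  }
  fcMeasures <- c(paste0("seg.", focal), paste0("intra.", focal))
  if (length(edgeCols)) {
    sigEdges <- out$focal_edges$outcome[out$focal_edges$significant]
    fcMeasures <- c(fcMeasures, sigEdges)
  }
  out$fc_cognition <- do.call(rbind, lapply(fcMeasures, function(fc) {
    runFamily(
      data, .COG_MEASURES, fc, cl$fc,
      family = paste0("fc_cognition:", fc), alpha = alpha
    )
  }))
  out
}

#' Write a simulated cohort to a directory as plain-text inputs
#'
#' Materializes the full input layout the pipeline consumes:
#' `timeseries/<subject>.tsv` (one per subject), `partition.tsv`,
#' `phenotypes.csv`, `battery.txt` and `truth.csv` (latent values, for
#' validation only — the pipeline never reads it).
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
simulateToDir <- function(spec, dir) {
  cohort <- generateCohort(spec)
  dir.create(file.path(dir, "timeseries"),
    recursive = TRUE, showWarnings = FALSE
  )
  for (ts in cohort$timeSeries) {
    writeTimeSeries(ts, file.path(
      dir, "timeseries", paste0(subjectId(ts), ".tsv")
    ))
  }
  writePartition(spec@partition, file.path(dir, "partition.tsv"))
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
    row.names = FALSE, quote = FALSE
  )
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
    row.names = FALSE, quote = FALSE
  )
  writeBattery(defaultBattery(), file.path(dir, "battery.txt"))
  invisible(dir)
}

#' Run the full pipeline on a directory of inputs
#'
#' Executes every stage in order on the layout written by
#' [simulateToDir()] (or assembled by hand in the same format):
#' connectivity (Pearson + Fisher z, then diagonal/negative zeroing),
#' segregation profiling including the focal network's edges, phenotype
#' scoring (handgrip from dynamometer trials when trial columns are
#' present, cognitive T-score composites), the five association
#' families, and mediation of each focal FC measure on the
#' handgrip-to-processing-speed and handgrip-to-global-cognition paths.
#' Every output table is written as TSV with fixed column order; a run
#' log records package version, seed, covariate set, dropped-row counts
#' and correlation-clip warnings. Reruns with an identical configuration
#' are byte-identical.
#'
#' @param inputDir directory with `timeseries/`, `partition.tsv`,
#'   `phenotypes.csv` and optionally `battery.txt`.
#' @param outDir output directory (created if needed).
#' @param covariateSet validation-analysis selector, see
#'   [runStandardFamilies()].
#' @param focal focal network label.
#' @param seed seed for the mediation bootstrap.
#' @param nBoot bootstrap resamples per mediation, default 5000.
#' @return Invisibly, a list with `profiles`, `families` (list),
#'   `mediation`, and `log` (character).
#' @export
runPipeline <- function(inputDir, outDir, covariateSet = "base",
                        focal = "salience_ventral_attention",
                        seed = 1L, nBoot = 5000) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(
    paste0("netsegfc ", as.character(utils::packageVersion("netsegfc"))),
    paste0("seed: ", seed),
    paste0("covariate set: ", covariateSet),
    paste0("focal network: ", focal)
  )
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
  }

  partition <- readPartition(file.path(inputDir, "partition.tsv"))
  phen <- utils::read.csv(
    file.path(inputDir, "phenotypes.csv"),
    stringsAsFactors = FALSE
  )
  batteryFile <- file.path(inputDir, "battery.txt")
  battery <- if (file.exists(batteryFile)) {
    readBattery(batteryFile)
  } else {
    defaultBattery()
  }

  tsFiles <- sort(list.files(
    file.path(inputDir, "timeseries"),
    pattern = "\\.(tsv|csv)$", full.names = TRUE
  ))
  tsIds <- sub("\\.[^.]*$", "", basename(tsFiles))
  missingTs <- setdiff(phen$subject_id, tsIds)
  missingPh <- setdiff(tsIds, phen$subject_id)
  if (length(missingTs) || length(missingPh)) {
    stop(
      "subject-id mismatch between time series and phenotypes",
      if (length(missingTs)) {
        paste0(
          "; no time series for: ", paste(missingTs, collapse = ", ")
        )
      } else "",
      if (length(missingPh)) {
        paste0(
          "; no phenotypes for: ", paste(missingPh, collapse = ", ")
        )
      } else ""
    )
  }

  nClip <- 0L
  matrices <- lapply(tsFiles, function(f) {
    ts <- readTimeSeries(f)
    m <- withCallingHandlers(
      computeFC(ts),
      warning = function(w) {
        if (grepl("clipped", conditionMessage(w))) {
          nClip <<- nClip + 1L
          invokeRestart("muffleWarning")
        }
      }
    )
    prepareMatrix(m)
  })
  note("subjects: ", length(matrices))
  note("correlation-clip warnings: ", nClip)

  edges <- networkPairs(partition, focal)
  profiles <- profileTable(matrices, partition, edges = edges)
  utils::write.table(profiles, file.path(outDir, "profiles.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )

  # handgrip from trials when present, else use the provided column
  trialCols <- c("grip_left_1", "grip_left_2", "grip_right_1", "grip_right_2")
  if (all(trialCols %in% names(phen))) {
    phen$handgrip <- vapply(seq_len(nrow(phen)), function(i) {
      handgripScore(
        c(phen$grip_left_1[i], phen$grip_left_2[i]),
        c(phen$grip_right_1[i], phen$grip_right_2[i])
      )
    }, numeric(1))
    note("handgrip scored from dynamometer trials (max per hand, then mean)")
  }
  note("sex encoding: 0 = female, 1 = male")
  cog <- scoreCognition(phen, battery)
  scored <- merge(
    phen[, setdiff(names(phen), battery$test), drop = FALSE],
    cog[, c("subject_id", setdiff(names(cog), names(phen))),
      drop = FALSE
    ],
    by = "subject_id"
  )
  data <- merge(scored, profiles, by = "subject_id")
  data <- data[order(data$subject_id), , drop = FALSE]

  dropMsgs <- character()
  families <- withCallingHandlers(
    runStandardFamilies(data,
      focal = focal, covariateSet = covariateSet
    ),
    message = function(m) {
      dropMsgs <<- c(dropMsgs, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  for (msg in unique(dropMsgs)) note("row filter: ", msg)
  for (fam in names(families)) {
    utils::write.table(
      families[[fam]],
      file.path(outDir, paste0("associations_", fam, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }

  cl <- .covariateLists(covariateSet)
  fcMeasures <- unique(c(
    paste0("seg.", focal), paste0("intra.", focal),
    if (!is.null(families$focal_edges)) {
      families$focal_edges$outcome[families$focal_edges$significant]
    }
  ))
  medRows <- list()
  for (fc in fcMeasures) {
    for (cogOut in c("processing_speed", "global")) {
      res <- mediate("handgrip", fc, cogOut,
        covariates = cl$fc, data = data,
        nBoot = nBoot, seed = seed
      )
      row <- cbind(
        data.frame(
          predictor = "handgrip", mediator = fc, outcome = cogOut,
          stringsAsFactors = FALSE
        ),
        mediationTable(res)
      )
      medRows[[length(medRows) + 1L]] <- row
    }
  }
  mediation <- do.call(rbind, medRows)
  utils::write.table(mediation, file.path(outDir, "mediation.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )

  writeLines(logLines, file.path(outDir, "runlog.txt"))
  invisible(list(
    profiles = profiles, families = families, mediation = mediation,
    log = logLines, data = data
  ))
}
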