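#' Assemble a pipeline run configuration
#'
#' @param samples path to the sample CSV.
#' @param weights_db path to the literature weight database CSV; `NULL`
#'   uses the packaged database.
#' @param standards path to a standards JSON; `NULL` uses the packaged
#'   defaults.
#' @param out output directory (created if needed).
#' @param n_sims,seed,negative_policy,normalize_draws simulation settings.
#' @param season `"dry"`, `"wet"` or `"all"`.
#' @param cbe_threshold charge-balance acceptance threshold in percent.
#' @param denominator sensitivity denominator, `"V"` or `"v"`.
#' @param ph_mode `"signed"` or `"symmetric"` (see [quality_rating()]).
#' @param sensitivity run the index-removal sensitivity stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(samples, weights_db = NULL, standards = NULL,
                       out = "iwqi_out", n_sims = 2000L, seed = 1L,
                       season = c("all", "dry", "wet"),
                       cbe_threshold = 5, denominator = c("V", "v"),
                       ph_mode = c("signed", "symmetric"),
                       negative_policy = c("clip", "resample"),
                       normalize_draws = TRUE, sensitivity = TRUE) {
  structure(list(samples = samples, weights_db = weights_db,
                 standards = standards, out = out,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 season = match.arg(season),
                 cbe_threshold = cbe_threshold,
                 denominator = match.arg(denominator),
                 ph_mode = match.arg(ph_mode),
                 negative_policy = match.arg(negative_policy),
                 normalize_draws = normalize_draws,
                 sensitivity = sensitivity),
            class = "run_config")
}

#' Run the full assessment pipeline
#'
#' validate -> charge-balance filter -> weighting (entropy, simulation,
#' integration) -> quality ratings and IWQI -> classification ->
#' sensitivity -> hydrochemical diagnostics, writing one CSV per report
#' plus a JSON run manifest into the output directory.  Any stage error
#' aborts with the stage named and removes the partial outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the output paths and the in-memory
#'   results (`iwqi` per season, `sensitivity`, `diagnostics`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("samples", "weights_db", "standards")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("config error: ", f, " file not found: ", config[[f]], call. = FALSE)
    }
  }
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name, comments = NULL) {
    p <- file.path(config$out, name)
    .write_csv_commented(df, p, c(sprintf("seed = %d", config$seed), comments))
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "read inputs"
    tab <- read_samples(config$samples)
    db <- if (is.null(config$weights_db)) literature_weight_db() else
      read_weight_db(config$weights_db)
    std <- if (is.null(config$standards)) default_standards() else
      read_standards(config$standards)
    if (config$season != "all") {
      keep <- which(tab$season == config$season)
      if (!length(keep)) stop("no samples with season ", config$season)
      tab <- .subset_samples(tab, keep)
    }

    stage <- "charge-balance filter"
    flt <- filter_by_cbe(tab, config$cbe_threshold)
    if (is.null(flt$table)) stop("no samples pass the CBE gate")
    tab <- flt$table
    cbe <- flt$cbe[tab$sample_id]

    seasons <- unique(tab$season)
    per_season <- lapply(seasons, function(s) {
      st <- .subset_samples(tab, which(tab$season == s))
      stage <<- paste0("IWQI scoring (", s, ")")
      res <- iwqi(st, standards = std, db = db, n_sims = config$n_sims,
                  seed = config$seed, negative_policy = config$negative_policy,
                  normalize_draws = config$normalize_draws,
                  ph_mode = config$ph_mode)
      sens <- NULL
      if (config$sensitivity) {
        stage <<- paste0("sensitivity (", s, ")")
        sens <- iwqi_sensitivity(st, standards = std, db = db,
                                 n_sims = config$n_sims, seed = config$seed,
                                 negative_policy = config$negative_policy,
                                 normalize_draws = config$normalize_draws,
                                 ph_mode = config$ph_mode,
                                 denominator = config$denominator)
      }
      list(season = s, table = st, iwqi = res, sensitivity = sens)
    })
    names(per_season) <- seasons

    stage <- "write reports"
    scores <- do.call(rbind, lapply(per_season, function(ps) {
      df <- as.data.frame(ps$iwqi)
      df$IWQI <- round(df$IWQI, 3)
      df$CBE <- round(unname(cbe[df$sample_id]), 3)
      df
    }))
    rownames(scores) <- NULL
    emit(scores, "scores.csv")
    if (nrow(flt$rejected)) emit(flt$rejected, "rejected_samples.csv")
    for (ps in per_season) {
      write_weight_report(ps$iwqi$weights,
                          file.path(config$out,
                                    paste0("weights_", ps$season, ".csv")))
      written <- c(written, file.path(config$out,
                                      paste0("weights_", ps$season, ".csv")))
      if (!is.null(ps$sensitivity)) {
        sd_ <- ps$sensitivity
        emit(data.frame(parameter = colnames(sd_$S),
                        mean_S_percent = round(unname(sd_$mean), 4),
                        min_S_percent = round(apply(sd_$S, 2L, min), 4),
                        max_S_percent = round(apply(sd_$S, 2L, max), 4),
                        row.names = NULL),
             paste0("sensitivity_", ps$season, ".csv"),
             paste0("denominator = ", sd_$denominator))
      }
    }

    stage <- "diagnostics"
    mq <- to_meq(tab)
    piper <- piper_coordinates(mq)
    piper$water_type <- classify_water_type(piper)
    piper$season <- tab$season
    num <- vapply(piper, is.numeric, logical(1))
    piper[num] <- lapply(piper[num], round, 4)
    emit(piper, "diagnostics_piper.csv")
    gb <- gibbs_ratios(tab, mq)
    gb$season <- tab$season
    gb[c("na_ratio", "cl_ratio")] <- lapply(gb[c("na_ratio", "cl_ratio")],
                                            round, 4)
    emit(gb, "diagnostics_gibbs.csv", "zone labels are heuristic rectangles")
    panel <- ion_ratio_panel(mq)
    emit(cbind(panel$reference_line,
               exchange_slope = round(panel$exchange_fit$slope, 6),
               exchange_intercept = round(panel$exchange_fit$intercept, 6)),
         "diagnostics_panels.csv")
    emit(descriptive_stats(tab, std), "descriptive_stats.csv")

    stage <- "manifest"
    manifest <- list(
      package = "iwqi",
      version = as.character(utils::packageVersion("iwqi")),
      seed = config$seed,
      config = config[setdiff(names(config), "out")],
      standards = std,
      n_samples = length(tab$sample_id),
      rejected_by_cbe = flt$rejected$sample_id
    )
    mpath <- file.path(config$out, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mpath)
    list(per_season = per_season, filtered = flt, outputs = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
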