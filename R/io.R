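#' Read a sample table from CSV
#'
#' Expected header: `sample_id`, `season`, then the parameter names (a
#' subset or all of the canonical catalog), one row per sample, decimal
#' point, UTF-8.  Optional `x`, `y` coordinate columns are carried along.
#'
#' @param path CSV path.
#' @param validate run [validate_sample_table()] (default TRUE).
#' @return A [sample_table].
#' @export
read_samples <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("samples file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (!nrow(df)) stop("empty samples file: ", path, call. = FALSE)
  need <- c("sample_id", "season")
  if (!all(need %in% names(df))) {
    stop("malformed header: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  coord_cols <- intersect(c("x", "y"), names(df))
  pcols <- setdiff(names(df), c(need, coord_cols))
  vals <- as.matrix(df[pcols])
  if (!is.numeric(vals)) {
    bad <- pcols[!vapply(df[pcols], is.numeric, logical(1))]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  coords <- if (length(coord_cols) == 2L) df[coord_cols] else NULL
  tab <- sample_table(vals, sample_id = df$sample_id, season = df$season,
                      coords = coords)
  if (validate) tab <- validate_sample_table(
    tab, .catalog_subset(param_catalog(), colnames(tab$values)))
  tab
}

#' Write a sample table to CSV
#'
#' @param x a [sample_table].
#' @param path output path.
#' @param header_comment optional character vector of provenance lines
#'   written as `#` comments above the header.
#' @return `path`, invisibly.
#' @export
write_samples <- function(x, path, header_comment = NULL) {
  stopifnot(inherits(x, "sample_table"))
  df <- as.data.frame(x)
  if (!is.null(x$coords)) df <- cbind(df, x$coords)
  .write_csv_commented(df, path, header_comment)
}

#' @keywords internal
.write_csv_commented <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a literature weight database from CSV
#'
#' One row per study: a `reference` label column followed by parameter
#' columns; blank cells mean the study did not weight that parameter.
#'
#' @param path CSV path.
#' @return data.frame (`reference` + numeric parameter columns with `NA`
#'   for missing).
#' @export
read_weight_db <- function(path) {
  if (!file.exists(path)) stop("weight database not found: ", path, call. = FALSE)
  db <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (!nrow(db)) stop("empty weight database: ", path, call. = FALSE)
  if (!"reference" %in% names(db)) {
    stop("weight database needs a 'reference' column", call. = FALSE)
  }
  pcols <- setdiff(names(db), "reference")
  for (p in pcols) db[[p]] <- as.numeric(db[[p]])
  neg <- pcols[vapply(db[pcols], function(v) any(v < 0, na.rm = TRUE), logical(1))]
  if (length(neg)) {
    stop("negative weight(s) in column(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  db
}

#' The packaged literature weight database
#'
#' 22 published groundwater-quality studies x 14 parameters, with blanks
#' where a study did not include a parameter.  Rows are used as printed
#' (several do not sum to 1; no renormalization is applied).
#'
#' @return data.frame as in [read_weight_db()].
#' @export
literature_weight_db <- function() {
  read_weight_db(system.file("extdata", "literature_weights.csv",
                             package = "iwqi", mustWork = TRUE))
}

#' Write a weight database to CSV
#' @param db data.frame as from [read_weight_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_db <- function(db, path) {
  df <- db
  for (p in setdiff(names(df), "reference")) {
    df[[p]] <- ifelse(is.na(df[[p]]), "", format(df[[p]], trim = TRUE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-parameter weight report
#'
#' Columns: parameter, entropy e, subjective weight W_s, literature mean
#' and SD, objective weight W_o, product-combined w and integrated W;
#' G_raw, G and the seed go into `#` header comments.
#'
#' @param wts result of [compute_weights()].
#' @param path output CSV path.
#' @param extra_comments additional provenance lines.
#' @return `path`, invisibly.
#' @export
write_weight_report <- function(wts, path, extra_comments = NULL) {
  df <- data.frame(parameter = names(wts$W),
                   e = as.numeric(wts$entropy),
                   W_s = as.numeric(wts$ws),
                   m = wts$stats$mean, s = wts$stats$sd,
                   W_o = as.numeric(wts$wo),
                   w = as.numeric(wts$w),
                   W = as.numeric(wts$W),
                   stringsAsFactors = FALSE)
  .write_csv_commented(df, path, c(
    sprintf("G_raw = %.12g; G = %.12g", wts$G_raw, wts$G),
    sprintf("n_sims = %d; seed = %d; negative_policy = %s",
            wts$ensemble$n_sims, wts$ensemble$seed,
            wts$ensemble$negative_policy),
    extra_comments))
}
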