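#' Construct a sample table
#'
#' Container for m water samples by n physicochemical parameters.  Values
#' are mg/L except pH (unitless).  Columns are matched against (a subset of)
#' the canonical [param_catalog()] order.
#'
#' @param values numeric matrix or data.frame, samples in rows, parameters in
#'   columns (column names required).
#' @param sample_id character vector of unique sample identifiers; defaults
#'   to `S01`, `S02`, ...
#' @param season `"dry"`, `"wet"` or `"unlabeled"`; recycled to one value
#'   per sample.
#' @param coords optional data.frame with columns `x`, `y` of planar
#'   coordinates per sample.
#' @return An object of class `sample_table`: a list with elements `values`
#'   (numeric matrix), `sample_id`, `season`, `coords`.
#' @export
sample_table <- function(values, sample_id = NULL, season = "unlabeled",
                         coords = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("sample values need parameter column names", call. = FALSE)
  }
  storage.mode(values) <- "double"
  m <- nrow(values)
  if (m < 1L || ncol(values) < 1L) stop("need at least one sample and one parameter",
                                        call. = FALSE)
  if (is.null(sample_id)) sample_id <- sprintf("S%02d", seq_len(m))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(sample_id) != m) stop("sample_id length != number of rows", call. = FALSE)
  season <- rep_len(as.character(season), m)
  bad_season <- setdiff(unique(season), c("dry", "wet", "unlabeled"))
  if (length(bad_season)) {
    stop("season must be dry, wet or unlabeled; got: ",
         paste(bad_season, collapse = ", "), call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    stopifnot(all(c("x", "y") %in% names(coords)), nrow(coords) == m)
  }
  rownames(values) <- sample_id
  structure(list(values = values, sample_id = sample_id, season = season,
                 coords = coords),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " parameters\n", sep = "")
  cat("seasons:", paste(sprintf("%s=%d", names(table(x$season)),
                                table(x$season)), collapse = ", "), "\n")
  print(utils::head(x$values, 4L))
  if (nrow(x$values) > 4L) cat("... (", nrow(x$values) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sample_table <- function(x, ...) {
  data.frame(sample_id = x$sample_id, season = x$season,
             as.data.frame(x$values), check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
dim.sample_table <- function(x) dim(x$values)

#' @keywords internal
.subset_samples <- function(x, idx) {
  sample_table(x$values[idx, , drop = FALSE], x$sample_id[idx], x$season[idx],
               if (!is.null(x$coords)) x$coords[idx, , drop = FALSE])
}

#' @keywords internal
.drop_parameter <- function(x, parameter) {
  keep <- setdiff(colnames(x$values), parameter)
  sample_table(x$values[, keep, drop = FALSE], x$sample_id, x$season, x$coords)
}

#' Coerce to a plain numeric sample matrix
#' @keywords internal
.as_sample_matrix <- function(x) {
  if (inherits(x, "sample_table")) return(x$values)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Validate a sample table against the parameter catalog
#'
#' Checks the schema (no unknown parameters), reorders columns to the
#' canonical catalog order, and enforces the physical invariants: no missing
#' cells (or row-dropping, if asked), non-negative concentrations, and pH
#' strictly inside (0, 14).
#'
#' @param x a [sample_table].
#' @param catalog a parameter catalog; defaults to the full 14-parameter
#'   [param_catalog()].  The table must contain every catalog parameter.
#' @param missing_policy `"error"` (default) rejects tables with missing
#'   cells; `"drop_row"` silently drops incomplete samples.
#' @return The validated table, columns in catalog order, with a character
#'   vector of notes in `attr(, "issues")` (empty when clean).
#' @export
validate_sample_table <- function(x, catalog = param_catalog(),
                                  missing_policy = c("error", "drop_row")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(x, "sample_table"))
  issues <- character(0)

  extra <- setdiff(colnames(x$values), catalog$parameter)
  if (length(extra)) {
    stop("schema error: parameter(s) not in catalog: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(catalog$parameter, colnames(x$values))
  if (length(absent)) {
    stop("schema error: catalog parameter(s) missing from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  vals <- x$values[, catalog$parameter, drop = FALSE]

  if (anyNA(vals)) {
    bad_rows <- which(rowSums(is.na(vals)) > 0)
    if (missing_policy == "error") {
      stop("missing cells in sample(s): ",
           paste(x$sample_id[bad_rows], collapse = ", "), call. = FALSE)
    }
    issues <- c(issues, paste0("dropped incomplete sample(s): ",
                               paste(x$sample_id[bad_rows], collapse = ", ")))
    keep <- setdiff(seq_len(nrow(vals)), bad_rows)
    if (!length(keep)) stop("no complete samples left after drop_row", call. = FALSE)
    x <- .subset_samples(x, keep)
    vals <- x$values[, catalog$parameter, drop = FALSE]
  }

  non_ph <- setdiff(colnames(vals), "pH")
  neg <- which(vals[, non_ph, drop = FALSE] < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    cells <- apply(neg, 1L, function(ij)
      paste0(x$sample_id[ij[1]], ":", non_ph[ij[2]]))
    stop("validation error: negative concentration at ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  if ("pH" %in% colnames(vals)) {
    bad_ph <- which(vals[, "pH"] <= 0 | vals[, "pH"] >= 14)
    if (length(bad_ph)) {
      stop("validation error: pH outside (0, 14) for sample(s): ",
           paste(x$sample_id[bad_ph], collapse = ", "), call. = FALSE)
    }
  }

  out <- sample_table(vals, x$sample_id, x$season, x$coords)
  attr(out, "issues") <- issues
  out
}
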