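#' Canonical parameter catalog
#'
#' The 14 physicochemical parameters handled by the package, in the canonical
#' column order used by every other function: pH, TDS, TH, the major cations
#' (Ca, Na, Mg, K), Fe, and the anions (HCO3, SO4, Cl, NO3_N, F, NO2_N).
#' Ionic parameters carry a charge, an equivalent mass (g/eq) and, for the
#' nitrogen species reported as N, the mass factor converting mg N/L to mg of
#' ion/L (NO3: 62/14, NO2: 46/14) applied before the meq conversion.
#'
#' @return A data.frame with columns `parameter`, `unit`, `role`
#'   (`"field"`, `"bulk"`, `"cation"`, `"anion"`), `charge`,
#'   `equivalent_mass` and `ion_mass_factor`.  Row order defines column
#'   order everywhere else in the package.
#' @examples
#' param_catalog()
#' @export
param_catalog <- function() {
  data.frame(
    parameter = c("pH", "TDS", "TH", "Ca", "Na", "Mg", "K", "Fe",
                  "HCO3", "SO4", "Cl", "NO3_N", "F", "NO2_N"),
    unit = c("unitless", rep("mg/L", 13L)),
    role = c("field", "bulk", "bulk",
             "cation", "cation", "cation", "cation", "cation",
             "anion", "anion", "anion", "anion", "anion", "anion"),
    charge = c(NA, NA, NA, 2, 1, 2, 1, 3, -1, -2, -1, -1, -1, -1),
    equivalent_mass = c(NA, NA, NA, 20.04, 22.99, 12.15, 39.10, 18.62,
                        61.02, 48.03, 35.45, 62.00, 19.00, 46.01),
    ion_mass_factor = c(NA, NA, NA, 1, 1, 1, 1, 1, 1, 1, 1,
                        62 / 14, 1, 46 / 14),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
.catalog_subset <- function(catalog, parameters) {
  missing <- setdiff(parameters, catalog$parameter)
  if (length(missing)) {
    stop("unknown parameter(s) not in catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  catalog[match(parameters, catalog$parameter), , drop = FALSE]
}

#' Five-class IWQI classification scheme
#'
#' Scores below 25 are Excellent (I), 25-50 Good (II), 50-75 Medium (III),
#' 75-100 Poor (IV) and above 100 Extremely Poor (V).  Intervals are
#' left-closed/right-open except the Poor class, which includes its upper
#' bound (a score of exactly 100 is Poor, matching the printed "<25" and
#' ">100" outer bands).
#'
#' @param boundaries strictly increasing numeric vector of the four interior
#'   class boundaries.
#' @param labels character vector of five class labels.
#' @return A list of class `classification_scheme`.
#' @export
classification_scheme <- function(boundaries = c(25, 50, 75, 100),
                                  labels = c("Excellent (I)", "Good (II)",
                                             "Medium (III)", "Poor (IV)",
                                             "Extremely Poor (V)")) {
  stopifnot(is.numeric(boundaries), !is.unsorted(boundaries, strictly = TRUE))
  if (length(labels) != length(boundaries) + 1L) {
    stop("need exactly one label per interval (", length(boundaries) + 1L,
         "), got ", length(labels), call. = FALSE)
  }
  structure(list(boundaries = boundaries, labels = labels),
            class = "classification_scheme")
}

#' Read a standards table from a JSON file
#'
#' The file maps each parameter name to `{T, C_ideal, limit}`: the scoring
#' standard value T (same units as the measurements), the ideal pure-water
#' value C_ideal (0 for everything except pH, where it is 7), and the
#' permissible limit used for exceedance (%SES) reporting.
#'
#' @param path path to a JSON standards file.
#' @return A data.frame with columns `parameter`, `T`, `C_ideal`, `limit`.
#' @seealso [default_standards()]
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) stop("standards file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path)
  raw <- raw[!grepl("^_", names(raw))]  # drop comment keys
  std <- data.frame(
    parameter = names(raw),
    T = vapply(raw, function(x) as.numeric(x[["T"]]), numeric(1)),
    C_ideal = vapply(raw, function(x) as.numeric(x[["C_ideal"]]), numeric(1)),
    limit = vapply(raw, function(x)
      if (is.null(x[["limit"]])) NA_real_ else as.numeric(x[["limit"]]),
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  bad <- std$parameter[std$T == std$C_ideal]
  if (length(bad)) {
    stop("standards: T must differ from C_ideal for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  std
}

#' Default standards table
#'
#' The packaged defaults: drinking-water limits for TH (450), HCO3 (250),
#' Fe (0.3) and NO3-N (20), class-III style values for TDS, Cl, SO4, Na, F
#' and NO2-N, documented placeholders for Ca, Mg and K, and pH scored
#' against the 7-8.5 band.  Override any value with your own file via
#' [read_standards()].
#'
#' @return A data.frame as in [read_standards()].
#' @export
default_standards <- function() {
  read_standards(system.file("extdata", "standards_default.json",
                             package = "iwqi", mustWork = TRUE))
}
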