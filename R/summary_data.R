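#' Summary-level genetic association data for Mendelian randomization
#'
#' Container for the two-sample summary statistics every estimator and
#' outlier detector in this package operates on: per-variant genetic
#' associations with one or more exposures (risk factors) and with a single
#' outcome, each with strictly positive standard errors, plus optional
#' per-variant exposure-exposure covariance blocks. Inputs are assumed
#' pre-harmonized (effect alleles aligned across the exposure and outcome
#' samples).
#'
#' @param beta_exposure numeric matrix (n variants x d exposures) of genetic
#'   associations with the exposures; a vector is treated as d = 1.
#' @param se_exposure matrix of the same shape with the standard errors
#'   (all > 0).
#' @param beta_outcome length-n vector of genetic associations with the
#'   outcome.
#' @param se_outcome length-n vector of standard errors (> 0).
#' @param variant_ids optional length-n character vector of unique variant
#'   labels (rsIDs or synthetic names); defaults to `snp_1 ... snp_n`.
#' @param exposure_cov optional d x d x n array of per-variant covariance
#'   blocks between the exposure association estimates. Each block must be
#'   symmetric with diagonal equal to `se_exposure^2` for that variant.
#'   When absent, all cross-exposure covariances are treated as zero, the
#'   common practice when only summary-level data are available.
#'
#' @return An object of class `mr_summary_data`: a list with elements
#'   `variant_ids`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `exposure_cov` (or `NULL`), and attributes `n` and `d`.
#' @export
#' @examples
#' d <- mr_summary_data(beta_exposure = c(0.2, 0.1), se_exposure = c(0.02, 0.02),
#'                      beta_outcome = c(0.4, -0.2), se_outcome = c(0.05, 0.06))
#' d
mr_summary_data <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                            variant_ids = NULL, exposure_cov = NULL) {
  beta_exposure <- as_matrix(beta_exposure)
  se_exposure <- as_matrix(se_exposure)
  beta_outcome <- as.numeric(beta_outcome)
  se_outcome <- as.numeric(se_outcome)
  n <- nrow(beta_exposure)
  d <- ncol(beta_exposure)
  if (n < 1L || d < 1L) {
    stop("need at least one variant and one exposure", call. = FALSE)
  }
  if (!identical(dim(se_exposure), dim(beta_exposure))) {
    stop("'beta_exposure' and 'se_exposure' dimensions disagree", call. = FALSE)
  }
  if (length(beta_outcome) != n || length(se_outcome) != n) {
    stop("outcome associations must have one entry per variant", call. = FALSE)
  }
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(n))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != n) {
    stop("'variant_ids' must have one label per variant", call. = FALSE)
  }
  if (anyDuplicated(variant_ids)) {
    stop("duplicate variant labels: ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "),
         call. = FALSE)
  }
  check_finite(beta_exposure, "beta_exposure")
  check_finite(beta_outcome, "beta_outcome")
  check_positive(se_exposure, "se_exposure", variant_ids)
  check_positive(se_outcome, "se_outcome", variant_ids)
  if (!is.null(exposure_cov)) {
    exposure_cov <- validate_exposure_cov(exposure_cov, se_exposure, variant_ids)
  }
  structure(
    list(variant_ids = variant_ids,
         beta_exposure = beta_exposure,
         se_exposure = se_exposure,
         beta_outcome = beta_outcome,
         se_outcome = se_outcome,
         exposure_cov = exposure_cov),
    n = n, d = d, class = "mr_summary_data")
}

as_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    x
  } else {
    matrix(as.numeric(x), ncol = 1L)
  }
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("non-finite values in '", what, "'", call. = FALSE)
  }
}

check_positive <- function(x, what, ids) {
  check_finite(x, what)
  bad <- which(apply(as_matrix(x) <= 0, 1L, any))
  if (length(bad)) {
    stop("non-positive standard error in '", what, "' for variant(s) ",
         paste(ids[bad], collapse = ", "), " (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
}

validate_exposure_cov <- function(exposure_cov, se_exposure, variant_ids) {
  n <- nrow(se_exposure)
  d <- ncol(se_exposure)
  if (!is.array(exposure_cov) || !identical(dim(exposure_cov), c(d, d, n))) {
    stop("'exposure_cov' must be a d x d x n array", call. = FALSE)
  }
  for (i in seq_len(n)) {
    block <- exposure_cov[, , i, drop = TRUE]
    block <- matrix(block, d, d)
    if (max(abs(block - t(block))) > 1e-8 * max(1, max(abs(block)))) {
      stop("covariance block for variant ", variant_ids[i], " is not symmetric",
           call. = FALSE)
    }
    if (max(abs(diag(block) - se_exposure[i, ]^2)) >
        1e-6 * max(1, max(se_exposure[i, ]^2))) {
      stop("covariance block diagonal for variant ", variant_ids[i],
           " does not equal the squared exposure standard errors", call. = FALSE)
    }
  }
  exposure_cov
}

#' @export
print.mr_summary_data <- function(x, ...) {
  cat("Two-sample MR summary data: ", attr(x, "n"), " variants, ",
      attr(x, "d"), " exposure(s)", sep = "")
  cat(if (is.null(x$exposure_cov)) ", no" else ", with",
      "exposure covariance blocks\n")
  invisible(x)
}

#' @export
`[.mr_summary_data` <- function(x, i, ...) {
  idx <- seq_along(x$variant_ids)
  names(idx) <- x$variant_ids
  i <- idx[i]
  mr_summary_data(
    beta_exposure = x$beta_exposure[i, , drop = FALSE],
    se_exposure = x$se_exposure[i, , drop = FALSE],
    beta_outcome = x$beta_outcome[i],
    se_outcome = x$se_outcome[i],
    variant_ids = x$variant_ids[i],
    exposure_cov = if (!is.null(x$exposure_cov)) x$exposure_cov[, , i, drop = FALSE])
}

#' Number of variants / exposures in a summary-data object
#' @param data an [mr_summary_data] object.
#' @return integer count.
#' @export
n_variants <- function(data) attr(data, "n")

#' @rdname n_variants
#' @export
n_exposures <- function(data) attr(data, "d")

#' Read a delimited summary-statistic table
#'
#' Reads a GWAS-summary-export style table with one row per variant and
#' columns `snp`, `beta_x1 ... beta_xd`, `se_x1 ... se_xd`, `beta_y`, `se_y`
#' (for a single exposure, `beta_x`/`se_x` are also accepted). The delimiter
#' is auto-detected from the file extension (`.csv` comma, otherwise tab) and
#' can be overridden. Row order is preserved.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects from the
#'   extension.
#' @param cov_path optional path to a long-format covariance file with
#'   columns `snp`, `j`, `k`, `cov` giving the covariance between the
#'   association estimates for exposures `j` and `k` at that variant
#'   (diagonal entries are filled from the squared standard errors and need
#'   not be supplied).
#' @return an [mr_summary_data] object.
#' @export
read_summary_table <- function(path, sep = NULL, cov_path = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  cols <- names(raw)
  if (!"snp" %in% cols) stop("missing required column 'snp'", call. = FALSE)
  bx_cols <- grep("^beta_x[0-9]*$", cols, value = TRUE)
  sx_cols <- grep("^se_x[0-9]*$", cols, value = TRUE)
  if (length(bx_cols) == 0L || length(sx_cols) != length(bx_cols)) {
    stop("expected matching 'beta_x<j>'/'se_x<j>' column pairs", call. = FALSE)
  }
  # order beta_x1, beta_x2, ... (plain beta_x treated as exposure 1)
  ord <- order(as.integer(sub("^beta_x", "", sub("^beta_x$", "beta_x1", bx_cols))))
  bx_cols <- bx_cols[ord]
  sx_cols <- sub("^beta", "se", bx_cols)
  if (!all(sx_cols %in% cols)) {
    stop("missing column(s): ", paste(setdiff(sx_cols, cols), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("beta_y", "se_y")) {
    if (!col %in% cols) stop("missing required column '", col, "'", call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value '", raw[[col]][bad[1L]], "' in column '", col,
           "' at line ", bad[1L] + 1L, call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing value in column '", col, "' at line ",
           which(is.na(v))[1L] + 1L, call. = FALSE)
    }
    v
  }
  beta_exposure <- vapply(bx_cols, num, numeric(nrow(raw)))
  se_exposure <- vapply(sx_cols, num, numeric(nrow(raw)))
  if (nrow(raw) == 1L) {
    beta_exposure <- matrix(beta_exposure, nrow = 1L)
    se_exposure <- matrix(se_exposure, nrow = 1L)
  }
  exposure_cov <- NULL
  if (!is.null(cov_path)) {
    exposure_cov <- read_exposure_cov(cov_path, raw$snp, se_exposure)
  }
  mr_summary_data(beta_exposure = beta_exposure, se_exposure = se_exposure,
                  beta_outcome = num("beta_y"), se_outcome = num("se_y"),
                  variant_ids = raw$snp, exposure_cov = exposure_cov)
}

read_exposure_cov <- function(cov_path, variant_ids, se_exposure) {
  tab <- utils::read.table(cov_path, header = TRUE,
                           sep = if (grepl("\\.csv$", cov_path)) "," else "\t",
                           stringsAsFactors = FALSE)
  need <- c("snp", "j", "k", "cov")
  if (!all(need %in% names(tab))) {
    stop("covariance file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- length(variant_ids)
  d <- ncol(se_exposure)
  arr <- array(0, dim = c(d, d, n))
  for (i in seq_len(n)) diag(arr[, , i]) <- se_exposure[i, ]^2
  idx <- match(tab$snp, variant_ids)
  if (anyNA(idx)) {
    stop("covariance file names unknown variant(s): ",
         paste(unique(tab$snp[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  for (r in seq_len(nrow(tab))) {
    j <- tab$j[r]; k <- tab$k[r]
    arr[j, k, idx[r]] <- tab$cov[r]
    arr[k, j, idx[r]] <- tab$cov[r]
  }
  arr
}

#' Write summary data back to a delimited table
#'
#' Inverse of [read_summary_table()]: numeric fields are written with 17
#' significant digits so a write/read round trip reproduces the object to
#' full double precision.
#'
#' @param data an [mr_summary_data] object.
#' @param path output path; extension decides the delimiter as in
#'   [read_summary_table()].
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(data, path) {
  d <- n_exposures(data)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  tab <- data.frame(snp = data$variant_ids, stringsAsFactors = FALSE)
  for (j in seq_len(d)) tab[[paste0("beta_x", j)]] <- fmt(data$beta_exposure[, j])
  for (j in seq_len(d)) tab[[paste0("se_x", j)]] <- fmt(data$se_exposure[, j])
  tab$beta_y <- fmt(data$beta_outcome)
  tab$se_y <- fmt(data$se_outcome)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
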