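new_outlier_report <- function(method, data, statistic, statistic_adj = NULL,
                               p_per_variant, threshold, threshold_desc,
                               flagged, estimate_full, estimate_post,
                               alpha, lambda = NULL, seed = NULL,
                               extra = list(), subclass = NULL) {
  out <- c(list(method = method,
                variant_ids = data$variant_ids,
                statistic_per_variant = statistic,
                statistic_adjusted = statistic_adj,
                p_per_variant = p_per_variant,
                threshold = threshold,
                threshold_description = threshold_desc,
                flagged = flagged,
                estimate_full = estimate_full,
                estimate_post = estimate_post,
                alpha = alpha, lambda = lambda, seed = seed), extra)
  class(out) <- c(subclass, "mr_outlier_report")
  out
}

#' @export
print.mr_outlier_report <- function(x, ...) {
  cat("MR outlier detection report: method '", x$method, "'\n", sep = "")
  if (!is.null(x$lambda)) {
    cat(sprintf("  inflation factor lambda-hat = %.4f\n", x$lambda))
  }
  cat(sprintf("  threshold: %s (critical value %.4f)\n",
              x$threshold_description, x$threshold))
  nfl <- length(x$flagged)
  cat("  flagged ", nfl, " of ", length(x$variant_ids), " variants",
      if (nfl) paste0(": ", paste(x$flagged, collapse = ", ")), "\n", sep = "")
  cat("  causal estimate, all variants:      ",
      paste(signif(x$estimate_full$theta, 4), collapse = ", "), "\n")
  cat("  causal estimate, outliers removed:  ",
      paste(signif(x$estimate_post$theta, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_outlier_report <- function(object, ...) {
  df <- data.frame(variant = object$variant_ids,
                   statistic = object$statistic_per_variant,
                   p_value = object$p_per_variant,
                   flagged = object$variant_ids %in% object$flagged,
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(object$statistic_adjusted)) {
    df$statistic_adjusted <- object$statistic_adjusted
    df <- df[, c("variant", "statistic", "statistic_adjusted", "p_value", "flagged")]
  }
  df
}

#' Write an outlier report to disk
#'
#' Writes a per-variant tab-separated table (variant, statistic, adjusted
#' statistic where applicable, p-value, flag) plus a JSON summary block
#' holding the method, the inflation factor (when applicable), the
#' threshold, and the causal estimates before and after removal.
#'
#' @param report an `mr_outlier_report` (e.g. from [mr_gcq()]).
#' @param path output path for the TSV table.
#' @param json_path output path for the JSON summary; defaults to `path`
#'   with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path,
                                 json_path = sub("\\.[^.]*$", ".json", path)) {
  stopifnot(inherits(report, "mr_outlier_report"))
  tab <- summary(report)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 17, format = "g"))
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path, call. = FALSE)
  summ <- list(method = report$method,
               alpha = report$alpha,
               lambda = report$lambda,
               threshold = report$threshold,
               threshold_description = report$threshold_description,
               n_variants = length(report$variant_ids),
               n_flagged = length(report$flagged),
               flagged = as.list(report$flagged),
               theta_full = as.list(unclass(report$estimate_full$theta)),
               se_full = as.list(unclass(report$estimate_full$se_theta)),
               theta_post = as.list(unclass(report$estimate_post$theta)),
               se_post = as.list(unclass(report$estimate_post$se_theta)),
               seed = report$seed)
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a written outlier report
#'
#' Counterpart of [write_outlier_report()] for round-tripping: returns the
#' per-variant table (with the flag column restored to logical) and the
#' parsed JSON summary block.
#'
#' @param path the TSV path given to [write_outlier_report()].
#' @param json_path the JSON path; same default rule.
#' @return list with elements `per_variant` (data.frame) and `summary` (list).
#' @export
read_outlier_report <- function(path,
                                json_path = sub("\\.[^.]*$", ".json", path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$flagged <- as.logical(tab$flagged)
  list(per_variant = tab, summary = jsonlite::read_json(json_path,
                                                        simplifyVector = TRUE))
}
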