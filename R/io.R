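# CSV dialects shared by the pipeline stages. Plain CSV, one header row,
# UTF-8, decimal point; numerics written with full float precision ("%.17g")
# so write-then-read round-trips exactly.

.write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_checked <- function(path, numeric_cols, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (nm in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]) &
                   !(df[[nm]] %in% c("NA", "", "NaN")))
    if (length(bad))
      stop("file '", path, "', column '", nm, "': non-numeric value(s) at ",
           "row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    df[[nm]] <- v
  }
  df
}

#' Read and write the sample-table CSV dialect
#'
#' Columns: `section_id`, `substrate`, `age_ma`, `value`, `sd`. Substrate
#' labels `plant_cuticle`, `plant_wood` and `bulk_om` are normalised to the
#' canonical classes used internally (`plant`, `bulk_om`); `carbonate` and
#' `sst` pass through.
#'
#' @param path File path.
#' @param samples Data frame in the dialect above.
#' @return `read_series_csv` returns the data frame; `write_series_csv`
#'   returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  df <- .read_csv_checked(path, c("age_ma", "value", "sd"),
                          c("section_id", "substrate", "age_ma", "value",
                            "sd"))
  if (anyDuplicated(df[, c("section_id", "substrate", "age_ma")]))
    warning("duplicated (section, substrate, age) rows in ", path)
  df$substrate[df$substrate %in% c("plant_cuticle", "plant_wood")] <- "plant"
  known <- c("plant", "bulk_om", "carbonate", "sst")
  bad <- which(!df$substrate %in% known)
  if (length(bad))
    stop("file '", path, "': unknown substrate at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(samples, path) {
  stopifnot(all(c("section_id", "substrate", "age_ma", "value", "sd")
                %in% names(samples)))
  .write_csv_full(samples[, c("section_id", "substrate", "age_ma", "value",
                              "sd")], path)
}

#' Read and write the true-history CSV dialect
#'
#' Columns: `age_ma`, `pco2_true`, `d13c_carb_true`, `sst_true`, plus
#' `d13c_p_true` when the forward-modelled plant record is available. Serves
#' as the test oracle alongside synthetic sample tables.
#'
#' @param path File path.
#' @param truth A `"true_history"` data frame.
#' @return The data frame (read) or `path`, invisibly (write).
#' @export
read_truth_csv <- function(path) {
  base <- c("age_ma", "pco2_true", "d13c_carb_true", "sst_true")
  df <- utils::read.csv(path, nrows = 1)
  num <- intersect(c(base, "d13c_p_true"), names(df))
  .read_csv_checked(path, num, base)
}

#' @rdname read_truth_csv
#' @export
write_truth_csv <- function(truth, path) {
  cols <- intersect(c("age_ma", "pco2_true", "d13c_carb_true", "sst_true",
                      "d13c_p_true"), names(truth))
  .write_csv_full(as.data.frame(truth)[, cols], path)
}

#' Read and write the stacked-curve CSV dialect
#'
#' Columns: `age_ma`, `center`, `se`, `n_local`. The span is stored in a
#' `# span:` comment-free sidecar attribute only in memory; the CSV holds
#' the curve itself.
#'
#' @param path File path.
#' @param stack A `"stacked_curve"` data frame.
#' @return The stacked curve (read) or `path`, invisibly (write).
#' @export
read_stack_csv <- function(path) {
  df <- .read_csv_checked(path, c("age_ma", "center", "se", "n_local"),
                          c("age_ma", "center", "se", "n_local"))
  if (anyDuplicated(df$age_ma))
    stop("file '", path, "': duplicated gridpoint age(s)")
  class(df) <- c("stacked_curve", "data.frame")
  df
}

#' @rdname read_stack_csv
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(all(c("age_ma", "center", "se", "n_local") %in% names(stack)))
  .write_csv_full(as.data.frame(stack)[, c("age_ma", "center", "se",
                                           "n_local")], path)
}

#' Read and write the reconstruction CSV dialect
#'
#' Columns: `age_ma`, `median_ppmv`, `p16_ppmv`, `p84_ppmv`, `n_valid`.
#'
#' @param path File path.
#' @param recon A `"pco2_reconstruction"` data frame.
#' @return A `"pco2_reconstruction"`-shaped data frame (read) or `path`
#'   (write).
#' @export
read_recon_csv <- function(path) {
  df <- .read_csv_checked(path,
                          c("age_ma", "median_ppmv", "p16_ppmv", "p84_ppmv",
                            "n_valid"),
                          c("age_ma", "median_ppmv", "p16_ppmv", "p84_ppmv",
                            "n_valid"))
  if (anyDuplicated(df$age_ma))
    stop("file '", path, "': duplicated gridpoint age(s)")
  out <- data.frame(age_ma = df$age_ma, median = df$median_ppmv,
                    p16 = df$p16_ppmv, p84 = df$p84_ppmv,
                    n_valid = df$n_valid)
  class(out) <- c("pco2_reconstruction", "data.frame")
  out
}

#' @rdname read_recon_csv
#' @export
write_recon_csv <- function(recon, path) {
  out <- data.frame(age_ma = recon$age_ma, median_ppmv = recon$median,
                    p16_ppmv = recon$p16, p84_ppmv = recon$p84,
                    n_valid = recon$n_valid)
  .write_csv_full(out, path)
}
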