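#' Read a delimited data matrix
#'
#' Reads a rectangular TSV/CSV table with a header row of variable names into
#' a [data_matrix()]. The delimiter is inferred from the file extension
#' (`.csv` comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param delimiter field separator, or `NULL` to infer.
#' @param types per-variable types or `"auto"` (see [data_matrix()]).
#' @return a [data_matrix()].
#' @export
read_matrix <- function(path, delimiter = NULL, types = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = delimiter, header = TRUE, check.names = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0) stop("no data rows in ", path)
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ", paste(bad, collapse = ", "))
  data_matrix(as.matrix(df), types = types)
}

#' Write a labeled matrix as TSV
#'
#' Full float precision, header row of column names, first column of row
#' names when present.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  df <- as.data.frame(m)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the differential edge list
#'
#' One TSV row per upper-triangle entry of the (thresholded) difference
#' matrix exceeding `threshold` in absolute value: 1-based indices `i`, `j`
#' (mirroring variable order), variable names, the estimated difference and
#' its sign (`+` means the conditional dependency increases from group 1 to
#' group 2). Rows are ordered by `(i, j)`.
#'
#' @param delta_hat matrix or `difference_estimate`.
#' @param names variable names (defaults to the matrix dimnames).
#' @param path output path.
#' @param threshold minimum absolute value for inclusion (default 0: all
#'   nonzeros).
#' @return the path, invisibly.
#' @export
write_edge_list <- function(delta_hat, names = NULL, path, threshold = 0) {
  m <- if (inherits(delta_hat, "difference_estimate")) delta_hat$delta_hat
       else as.matrix(delta_hat)
  if (is.null(names)) names <- colnames(m)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(m)))
  ut <- which(upper.tri(m) & abs(m) > threshold, arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  df <- data.frame(i = ut[, 1], j = ut[, 2],
                   gene_i = names[ut[, 1]], gene_j = names[ut[, 2]],
                   delta = m[ut],
                   sign = ifelse(m[ut] > 0, "+", "-"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Fit and tune a differential network from two data matrices
#'
#' End-to-end convenience wrapper: estimates both groups' correlation
#' matrices (rank-based latent correlations for `method = "RDN"`, Pearson for
#' `"DDN"`), solves the constrained l1 difference estimator over a lambda
#' path (or at one fixed lambda), tunes by AIC, and thresholds the result.
#'
#' @param data1,data2 [data_matrix()] objects (or matrices, typed by `types`).
#' @param method `"RDN"` (rank-based, the default) or `"DDN"` (Pearson).
#' @param types type handling for plain-matrix inputs: `"auto"`, or
#'   `"continuous"`/`"binary"` to force all columns.
#' @param lambda `"auto"` for AIC tuning over a path, or a fixed value.
#' @param loss AIC loss, see [loss_value()].
#' @param rho ADMM penalty parameter.
#' @param threshold support threshold for the returned edge set.
#' @param nlambda path length under `lambda = "auto"`.
#' @return list with `estimate` (selected `difference_estimate`),
#'   `thresholded`, `tuning` (a `tuning_result`, or `NULL` for fixed
#'   lambda), `s1`, `s2` and the call parameters.
#' @export
differential_network <- function(data1, data2, method = c("RDN", "DDN"),
                                 types = "auto", lambda = "auto",
                                 loss = c("F", "Linf", "spectral", "L1"),
                                 rho = 1, threshold = 1e-5, nlambda = 50L) {
  method <- match.arg(method)
  loss <- match.arg(loss)
  if (identical(types, "mixed")) types <- "auto"
  data1 <- as_data_matrix(data1, types = types)
  data2 <- as_data_matrix(data2, types = types)
  if (ncol(data1$values) != ncol(data2$values))
    stop("the two groups must share the same variables")
  # with binary variables present the rank estimates carry gross
  # bridge-inversion noise at moderate n; the nearest-PSD projection pools
  # information across pairs and suppresses it (see latent_correlation docs)
  proj <- any(c(data1$types, data2$types) == "binary")
  s <- if (method == "RDN")
    list(latent_correlation(data1, psd = proj)$matrix,
         latent_correlation(data2, psd = proj)$matrix)
  else
    list(pearson_correlation(data1), pearson_correlation(data2))
  if (identical(lambda, "auto")) {
    path <- solve_path(s[[1]], s[[2]], nlambda = nlambda, rho = rho)
    tuning <- aic_select(path, s[[1]], s[[2]], nrow(data1$values),
                         nrow(data2$values), loss)
    est <- tuning$estimate
  } else {
    est <- admm_solve(s[[1]], s[[2]], as.numeric(lambda), rho = rho)
    tuning <- NULL
  }
  list(estimate = est, thresholded = threshold_support(est, threshold),
       tuning = tuning, s1 = s[[1]], s2 = s[[2]], method = method,
       loss = loss, threshold = threshold)
}
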