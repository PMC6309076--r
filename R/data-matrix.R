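#' Construct a typed data matrix
#'
#' Bundles one group's observations-by-variables matrix with a per-variable
#' type mask. Binary variables are the observed 0/1 indicators of a latent
#' continuous variable exceeding an unknown cutoff; continuous variables are
#' observed directly (possibly after an unknown monotone marginal transform).
#'
#' @param values numeric matrix (or data frame), observations in rows.
#' @param types per-variable types: `"continuous"`/`"binary"` vector recycled
#'   to the number of columns, or `"auto"` to flag as binary every column
#'   whose values lie in \{0, 1\}.
#' @param group_label free-text label carried through to outputs.
#' @return A `data_matrix` object: list with `values`, `types`, `group_label`.
#' @examples
#' x <- data_matrix(cbind(a = rnorm(5), b = c(0, 1, 1, 0, 1)), types = "auto")
#' x$types
#' @export
data_matrix <- function(values, types = "auto", group_label = "") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (nrow(values) < 2L) stop("need at least 2 observations")
  if (anyNA(values)) stop("missing values are not supported")
  p <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("V", seq_len(p))
  if (identical(types, "auto")) {
    types <- unname(ifelse(apply(values, 2L, function(col)
      all(col %in% c(0, 1))), "binary", "continuous"))
  } else {
    types <- rep_len(types, p)
  }
  if (!all(types %in% c("continuous", "binary")))
    stop("types must be 'continuous' or 'binary'")
  bad <- which(types == "binary" &
                 apply(values, 2L, function(col) !all(col %in% c(0, 1))))
  if (length(bad))
    stop("column(s) declared binary but not in {0,1}: ",
         paste(colnames(values)[bad], collapse = ", "))
  structure(list(values = values, types = types, group_label = group_label),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d observations x %d variables (%d binary)%s\n",
              nrow(x$values), ncol(x$values), sum(x$types == "binary"),
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]")
              else ""))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

as_data_matrix <- function(x, types = "auto") {
  if (inherits(x, "data_matrix")) x else data_matrix(x, types = types)
}
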