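#' Feature-by-sample matrices
#'
#' The pipeline's central container is a plain numeric matrix with feature
#' row names, sample column names and a `layer` attribute naming the omics
#' layer. Missing measurements are `NA`, never zero. The cnv layer is
#' restricted to discrete copy-number scores in \{-2, -1, 0, 1, 2\}.
#'
#' @param values numeric matrix with unique row and column names.
#' @param layer one of `"mrna"`, `"protein"`, `"phospho"`, `"cnv"`,
#'   `"activity"`.
#' @return the validated matrix with a `layer` attribute.
#' @export
feature_matrix <- function(values, layer = c("mrna", "protein", "phospho",
                                             "cnv", "activity")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry feature row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate feature ids: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  if (layer == "cnv") {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% -2:2))
      stop("cnv layer values must lie in {-2,-1,0,1,2}; found ",
           paste(unique(v[!v %in% -2:2]), collapse = ", "))
  }
  attr(values, "layer") <- layer
  values
}

#' Read a feature-by-sample matrix from tab-separated text
#'
#' Expects a header row of sample ids, a first column of feature ids and
#' `NA` for missing cells. Values are parsed as doubles; a non-numeric cell
#' or a duplicated id is a hard error naming the offender.
#'
#' @param path file path.
#' @param layer omics layer label, validated as in [feature_matrix()].
#' @return numeric matrix with a `layer` attribute.
#' @seealso [write_matrix()] for the bit-identical round-trip counterpart.
#' @export
read_matrix <- function(path, layer = "mrna") {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
  dup <- header[duplicated(header)]       # read.table would silently rename
  if (length(dup)) stop("duplicate sample ids: ",
                        paste(unique(dup), collapse = ", "))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = "NA",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("matrix file needs a feature-id column plus samples")
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(body)[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(body))
  feature_matrix(num, layer)
}

#' Write a feature-by-sample matrix as tab-separated text
#'
#' Finite values are serialised with 17 significant digits so that
#' `read_matrix(write_matrix(x))` reproduces `x` bit-identically; missing
#' cells are written as `NA`.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file path.
#' @param id_col header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_col = "feature_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  chr <- array("NA", dim = dim(x))
  ok <- !is.na(x)
  chr[ok] <- sprintf("%.17g", x[ok])
  lines <- c(paste(c(id_col, colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# deterministic writer for result data frames (no quoting, NA as "NA")
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- rep(NA_character_, length(v))
    out[!is.na(v)] <- sprintf("%.17g", v[!is.na(v)])
    out
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
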