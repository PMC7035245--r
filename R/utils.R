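#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   left_join bind_rows n desc across all_of row_number
#' @importFrom stats prcomp kmeans phyper p.adjust cor.test rnbinom rnorm
#'   rlnorm rbeta runif pnorm pt pchisq dnbinom uniroot sd var quantile
#'   wilcox.test prop.test fisher.test setNames dist
#' @importFrom utils head
NULL

# Abort with a consistent class so callers can test on condition class.
stop_conecod <- function(msg, class = "conecod_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_conecod(msg)
}

# Geometric mean; all values must be positive.
geom_mean <- function(x) exp(mean(log(x)))

# Derive a per-stage 31-bit seed from a global seed and a stage index so each
# pipeline stage can be re-run in isolation with the same stream.
derive_seed <- function(seed, stage) {
  # Lehmer step; 48271 * 2^31 stays exact in double arithmetic
  as.integer((((as.double(seed) %% 2147483647) * 48271) %% 2147483647 +
                stage * 97) %% 2147483647)
}

# Validate a genes x cells count matrix; returns it as dgCMatrix.
check_counts <- function(counts, arg = "counts") {
  if (is.matrix(counts)) counts <- methods::as(counts, "CsparseMatrix")
  assert_that(methods::is(counts, "sparseMatrix"),
              paste0("`", arg, "` must be a (sparse) genes x cells matrix"))
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              paste0("`", arg, "` needs gene ids as rownames and barcodes as colnames"))
  assert_that(!anyDuplicated(rownames(counts)), "duplicate gene ids")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate cell barcodes")
  assert_that(all(counts@x >= 0), "counts must be non-negative")
  counts
}

# Resolve a cell selection (barcodes, logical mask, or integer index) against
# the columns of a matrix; returns barcodes.
resolve_cells <- function(cells, mat, arg = "cells") {
  bc <- colnames(mat)
  if (is.logical(cells)) {
    assert_that(length(cells) == length(bc),
                paste0("logical `", arg, "` must match the number of cells"))
    return(bc[cells])
  }
  if (is.numeric(cells)) return(bc[cells])
  missing <- setdiff(cells, bc)
  assert_that(length(missing) == 0,
              paste0(length(missing), " barcodes in `", arg, "` not found in matrix"))
  cells
}

is_ribosomal <- function(genes) grepl("^RP[LS]", genes)
is_mito <- function(genes, prefix = "MT-") startsWith(genes, prefix)

#' @importFrom methods as is new
NULL
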