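#' Fraction of a target gene set overlapped by a selection
#'
#' The denominator is the full target-set size, so an incomplete universe
#' simply caps the attainable fraction (34 of a 475-gene set gives 7.2%).
#'
#' @param target_set Character vector of target genes (non-empty, unique).
#' @param selection Character vector of selected genes.
#' @return `length(intersect(target_set, selection)) / length(target_set)`.
#' @export
overlap_fraction <- function(target_set, selection) {
  if (length(target_set) == 0)
    stop_conecod("target set is empty", class = "conecod_validation_error")
  length(intersect(target_set, selection)) / length(unique(target_set))
}

#' Monte-Carlo resampling null for gene-set overlap
#'
#' Each iteration draws `k` genes uniformly without replacement from the
#' universe and records the overlap fraction with the target set.
#'
#' @param universe Character vector of background genes (size N).
#' @param target_set Target gene set (overlap counted via its members present
#'   in the universe).
#' @param k Draw size (<= N).
#' @param n_iterations Number of resampling iterations.
#' @param seed Integer seed; fixes the null sample.
#' @return Numeric vector of `n_iterations` null overlap fractions.
#' @export
resampling_null <- function(universe, target_set, k, n_iterations = 1000,
                            seed = 1L) {
  n <- length(universe)
  if (k > n)
    stop_conecod("draw size k exceeds the universe size",
                 class = "conecod_validation_error")
  in_set <- universe %in% target_set
  set.seed(seed)
  vapply(seq_len(n_iterations), function(i)
    sum(in_set[sample.int(n, k)]) / length(unique(target_set)),
    numeric(1))
}

#' Resampling enrichment test with closed-form and hypergeometric oracles
#'
#' Compares the observed overlap fraction of a gene selection with a target
#' set against the Monte-Carlo resampling null, reporting: a two-tailed
#' one-sample t of the null sample against the observed value, an add-one
#' empirical p (two-tailed by doubling the smaller tail), the exact
#' hypergeometric upper-tail p, and the closed-form expected fraction
#' `|S intersect U| * k / (N * |S|)`.
#'
#' @param universe Background gene list (size N).
#' @param target_set Target gene set (size |S|; |S intersect U| members lie in
#'   the universe).
#' @param selection Selected genes, a subset of the universe (size k).
#' @param n_iterations Resampling iterations (>= 2 for the t p-value).
#' @param seed Integer seed.
#' @return A `conecod_enrichment` object; see [tidy.conecod_enrichment()].
#' @export
enrichment_test <- function(universe, target_set, selection,
                            n_iterations = 1000, seed = 1L) {
  assert_that(all(selection %in% universe), "selection must lie in the universe")
  k <- length(unique(selection))
  n <- length(unique(universe))
  s_total <- length(unique(target_set))
  s_in_u <- length(intersect(target_set, universe))
  observed_overlap <- length(intersect(target_set, selection))
  observed <- observed_overlap / s_total
  null_fr <- resampling_null(universe, target_set, k, n_iterations, seed)
  expected <- s_in_u * k / (n * s_total)
  if (n_iterations >= 2) {
    tstat <- (mean(null_fr) - observed) / (sd(null_fr) / sqrt(n_iterations))
    p_t <- max(2 * pt(-abs(tstat), df = n_iterations - 1), 1e-300)
  } else {
    warn("n_iterations < 2: t p-value unavailable")
    p_t <- NA_real_
  }
  upper <- (1 + sum(null_fr >= observed)) / (n_iterations + 1)
  lower <- (1 + sum(null_fr <= observed)) / (n_iterations + 1)
  p_emp <- min(1, 2 * min(upper, lower))
  p_hyper <- max(phyper(observed_overlap - 1, s_in_u, n - s_in_u, k,
                        lower.tail = FALSE), 1e-300)
  structure(list(
    observed_fraction = observed, observed_overlap = observed_overlap,
    null_fractions = null_fr, null_mean = mean(null_fr),
    null_sd = sd(null_fr), expected_fraction_closed_form = expected,
    p_t = p_t, p_empirical = p_emp, p_hypergeom = p_hyper,
    sizes = c(N = n, S = s_total, S_in_U = s_in_u, k = k),
    n_iterations = n_iterations, seed = seed
  ), class = "conecod_enrichment")
}

#' @export
print.conecod_enrichment <- function(x, ...) {
  s <- x$sizes
  cat(sprintf("Gene-set resampling enrichment (N=%d, |S|=%d, |S in U|=%d, k=%d)\n",
              s["N"], s["S"], s["S_in_U"], s["k"]))
  cat(sprintf("  observed: %d genes (%.1f%%)   expected: %.1f%% (closed form)\n",
              x$observed_overlap, 100 * x$observed_fraction,
              100 * x$expected_fraction_closed_form))
  cat(sprintf("  null mean over %d iterations: %.2f%% (sd %.2f%%)\n",
              x$n_iterations, 100 * x$null_mean, 100 * x$null_sd))
  cat(sprintf("  p (t) = %.3g   p (empirical) = %.3g   p (hypergeometric) = %.3g\n",
              x$p_t, x$p_empirical, x$p_hypergeom))
  invisible(x)
}

#' Over-representation analysis for user-supplied gene sets
#'
#' One hypergeometric upper-tail test per set over a common background, with
#' Benjamini-Hochberg adjustment. Sets with no background member are dropped
#' with a warning.
#'
#' @param gene_sets Named list of character vectors (or a GMT file path read
#'   with [read_gene_sets()]).
#' @param query Selected genes; must be a subset of the background.
#' @param background Background gene universe.
#' @return Tibble: set, n_set, n_in_background, overlap, expected, fold,
#'   p, p_adj.
#' @export
ora <- function(gene_sets, query, background) {
  if (!all(query %in% background))
    stop_conecod("query must be a subset of the background",
                 class = "conecod_validation_error")
  background <- unique(background)
  query <- unique(query)
  n <- length(background); k <- length(query)
  in_bg <- vapply(gene_sets, function(s) length(intersect(s, background)),
                  integer(1))
  if (any(in_bg == 0)) {
    warn(paste("gene sets with no background member dropped:",
               paste(names(gene_sets)[in_bg == 0], collapse = ", ")))
    gene_sets <- gene_sets[in_bg > 0]
  }
  res <- purrr::map_dfr(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], background)
    ov <- length(intersect(s, query))
    expected <- length(s) * k / n
    tibble(set = nm, n_set = length(unique(gene_sets[[nm]])),
           n_in_background = length(s), overlap = ov, expected = expected,
           fold = ifelse(expected > 0, ov / expected, NA_real_),
           p = phyper(ov - 1, length(s), n - length(s), k, lower.tail = FALSE))
  })
  res |> mutate(p_adj = p.adjust(.data$p, "BH")) |> arrange(.data$p)
}

#' Read gene sets from a plain list or GMT file
#'
#' Plain format: one gene per line, one set per file (set named after the
#' file). GMT: one set per line, tab-separated `name description gene ...`.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (grepl("\\.gmt$", path)) {
    parts <- strsplit(lines, "\t")
    setNames(lapply(parts, function(p) unique(p[-(1:2)])),
             vapply(parts, `[[`, character(1), 1))
  } else {
    setNames(list(unique(trimws(lines))),
             sub("\\.[^.]*$", "", basename(path)))
  }
}
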