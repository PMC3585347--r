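#' Build an annotation map for enrichment testing
#'
#' Validates a term -> gene-set mapping against a background universe.
#' Terms with no genes are rejected; annotated genes outside the
#' universe are dropped with a warning.
#'
#' @param terms named list of character vectors (term id -> gene ids).
#' @param universe background gene universe.
#' @param term_names optional named character vector of display names.
#' @return object of class `annotation_map`: list with `terms`,
#'   `term_names`, `universe`.
#' @export
annotation_map <- function(terms, universe, term_names = NULL) {
  if (length(terms) == 0L || is.null(names(terms))) {
    stop("terms must be a non-empty named list", call. = FALSE)
  }
  universe <- unique(universe)
  terms <- lapply(terms, unique)
  dropped <- unique(unlist(lapply(terms, setdiff, y = universe)))
  if (length(dropped) > 0L) {
    warning(length(dropped),
            " annotated gene(s) outside the universe were dropped",
            call. = FALSE)
    terms <- lapply(terms, intersect, y = universe)
  }
  empty <- vapply(terms, length, integer(1)) == 0L
  if (any(empty)) {
    stop("terms with empty gene sets: ",
         paste(names(terms)[empty], collapse = ", "), call. = FALSE)
  }
  if (is.null(term_names)) {
    term_names <- setNames(names(terms), names(terms))
  }
  structure(list(terms = terms, term_names = term_names,
                 universe = universe),
            class = "annotation_map")
}

#' Read a GMT annotation file
#'
#' Standard GMT layout: one term per line, tab-separated as
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Two-column
#' TSV files (`gene_id`, `term_id`) are also accepted.
#'
#' @param path GMT or two-column TSV file.
#' @param universe background universe; defaults to all annotated genes.
#' @return an `annotation_map`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (all(n_fields == 2L) && !any(grepl("\t.*\t", lines))) {
    # two-column gene -> term table (with or without header)
    g <- vapply(fields, `[`, character(1), 1L)
    t <- vapply(fields, `[`, character(1), 2L)
    if (g[1L] %in% c("gene_id", "gene")) {
      g <- g[-1L]; t <- t[-1L]
    }
    terms <- split(g, t)
    names_v <- setNames(names(terms), names(terms))
  } else {
    terms <- lapply(fields, function(f) f[-(1:2)])
    names(terms) <- vapply(fields, `[`, character(1), 1L)
    names_v <- setNames(vapply(fields, `[`, character(1), 2L),
                        names(terms))
  }
  if (is.null(universe)) universe <- unique(unlist(terms))
  annotation_map(terms, universe, names_v)
}

#' Enrichment ratio of a category
#'
#' `Re = (n_f / n) / (N_f / N)`: the flagged fraction within the
#' category relative to the flagged fraction in the whole reference
#' list. `Re > 1` means over-representation.
#'
#' @param n_f flagged genes inside the category.
#' @param n category size.
#' @param N_f flagged genes in the universe.
#' @param N universe size.
#' @return enrichment ratio(s); vectorized.
#' @examples
#' enrichment_ratio(10, 20, 100, 1000)  # 5
#' @export
enrichment_ratio <- function(n_f, n, N_f, N) {
  if (any(n <= 0) || any(N_f <= 0) || any(N <= 0)) {
    stop("n, N_f and N must be positive", call. = FALSE)
  }
  (n_f / n) / (N_f / N)
}

#' Two-sided Fisher exact test on a 2x2 enrichment table
#'
#' Exact test of category membership against flagged status, from the
#' margins (`n_f`, `n`, `N_f`, `N`). The two-sided p-value sums all
#' hypergeometric outcomes whose probability does not exceed the
#' observed table's (with the customary 1e-7 relative tolerance for
#' floating-point ties).
#'
#' @inheritParams enrichment_ratio
#' @return two-sided p-value; vectorized over `n_f`.
#' @export
fisher_exact_2x2 <- function(n_f, n, N_f, N) {
  cells_ok <- n_f >= 0 & (n - n_f) >= 0 & (N_f - n_f) >= 0 &
    (N - n - N_f + n_f) >= 0
  if (!all(cells_ok)) {
    stop("margins imply a negative cell count", call. = FALSE)
  }
  k <- max(length(n_f), length(n), length(N_f), length(N))
  n_f <- rep_len(n_f, k); n <- rep_len(n, k)
  N_f <- rep_len(N_f, k); N <- rep_len(N, k)
  vapply(seq_len(k), function(i) {
    support <- max(0, n[i] + N_f[i] - N[i]):min(n[i], N_f[i])
    probs <- dhyper(support, N_f[i], N[i] - N_f[i], n[i])
    obs <- probs[support == n_f[i]]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Pearson chi-squared test on a 2x2 enrichment table
#'
#' The classical category-association test on the same margins as
#' [fisher_exact_2x2()], with 1 degree of freedom. Continuity
#' correction is off by default to match the plain Pearson statistic.
#'
#' @inheritParams enrichment_ratio
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic` and `p_value`.
#' @export
chi2_category <- function(n_f, n, N_f, N, correct = FALSE) {
  o <- c(n_f, n - n_f, N_f - n_f, N - n - N_f + n_f)
  if (any(o < 0)) stop("margins imply a negative cell count",
                       call. = FALSE)
  m <- matrix(o, nrow = 2L)  # rows: flagged/not; cols: in/out category
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(e == 0)) {
    stop("zero expected cell count; use fisher_exact_2x2 instead",
         call. = FALSE)
  }
  d <- abs(m - e)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 1L,
                                          lower.tail = FALSE))
}

#' Gene-set enrichment over an annotation map
#'
#' For every term, computes the enrichment ratio, the two-sided Fisher
#' exact p-value, the chi-squared p-value (NA when an expected cell is
#' zero) and the BH-FDR across all tested terms; a term is selected
#' when its p-value and FDR both clear the cutoffs.
#'
#' @param flagged character vector of flagged (e.g. differentially
#'   expressed) gene ids; must be drawn from the universe, outsiders
#'   are dropped with a warning.
#' @param annotation an `annotation_map`.
#' @param p_max,fdr_max selection cutoffs (default 0.05 each).
#' @param method p-value used for FDR and selection: `"fisher"`
#'   (default, exact at small counts) or `"chi2"`.
#' @return data frame of class `enrichment_result`, one row per term:
#'   `term_id`, `term_name`, `n_f`, `n`, `N_f`, `N`, `Re`, `p_fisher`,
#'   `p_chi2`, `fdr`, `selected`.
#' @export
enrich <- function(flagged, annotation, p_max = 0.05, fdr_max = 0.05,
                   method = c("fisher", "chi2")) {
  method <- match.arg(method)
  stopifnot(inherits(annotation, "annotation_map"))
  flagged <- unique(flagged)
  if (length(flagged) == 0L) {
    stop("flagged gene set is empty", call. = FALSE)
  }
  outside <- setdiff(flagged, annotation$universe)
  if (length(outside) > 0L) {
    warning(length(outside), " flagged gene(s) outside the universe ",
            "were dropped: ",
            paste(head(outside, 5L), collapse = ", "), call. = FALSE)
    flagged <- intersect(flagged, annotation$universe)
    if (length(flagged) == 0L) {
      stop("no flagged genes remain inside the universe", call. = FALSE)
    }
  }
  N <- length(annotation$universe)
  N_f <- length(flagged)
  n <- vapply(annotation$terms, length, integer(1))
  n_f <- vapply(annotation$terms,
                function(g) length(intersect(g, flagged)), integer(1))

  p_fisher <- vapply(seq_along(n),
                     function(i) fisher_exact_2x2(n_f[i], n[i], N_f, N),
                     numeric(1))
  p_chi2 <- vapply(seq_along(n), function(i) {
    tryCatch(chi2_category(n_f[i], n[i], N_f, N)$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
  p_sel <- if (method == "fisher") p_fisher else p_chi2
  fdr <- rep(NA_real_, length(p_sel))
  ok <- !is.na(p_sel)
  fdr[ok] <- bh_fdr(p_sel[ok])

  out <- data.frame(
    term_id = names(annotation$terms),
    term_name = unname(annotation$term_names[names(annotation$terms)]),
    n_f = n_f, n = n, N_f = N_f, N = N,
    Re = enrichment_ratio(n_f, n, N_f, N),
    p_fisher = p_fisher, p_chi2 = p_chi2, fdr = fdr,
    selected = ok & p_sel < p_max & fdr < fdr_max,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("enrichment_result", "data.frame")
  out[order(out$p_fisher), ]
}
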