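# GO-term enrichment of one interacting-OG set against another, with per-OG
# gene resampling (OGs can contain multiple genes; one gene per OG is drawn
# per repeat and the enrichment recomputed).

#' Draw one gene per OG
#'
#' @param ogs character vector of OG ids.
#' @param og_to_genes named list: OG -> character vector of member genes.
#' @param seed RNG seed.
#' @return named character vector: OG -> sampled gene.
#' @export
sample_genes <- function(ogs, og_to_genes, seed = 1L) {
  missing_og <- ogs[!vapply(ogs, function(og) length(og_to_genes[[og]]) >= 1,
                            logical(1))]
  abort_if(length(missing_og) > 0, "OG(s) with no genes in the mapping: %s",
           paste(utils::head(missing_og, 5), collapse = ", "))
  withr::with_seed(seed, {
    genes <- vapply(ogs, function(og) {
      g <- og_to_genes[[og]]
      if (length(g) == 1) g else sample(g, 1)
    }, character(1))
  })
  genes
}

#' Fold-enrichment score
#'
#' `(n/m) / (k/q)`: the proportion of sample genes carrying a GO term over
#' the proportion of population genes carrying it.
#'
#' @param n sample genes with the term (overlap).
#' @param m sample size.
#' @param k population genes with the term.
#' @param q population size.
#' @return numeric score (>= 0); errors when `k = 0` (undefined).
#' @export
enrichment_score <- function(n, m, k, q) {
  abort_if(m <= 0 || q <= 0, "sample and population sizes must be positive")
  abort_if(k <= 0, "enrichment score undefined for k = 0 (term absent from population)")
  (n / m) / (k / q)
}

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing `n` or more term-carrying genes when drawing `m`
#' genes from a universe of `q` genes of which `k` carry the term.
#'
#' @inheritParams enrichment_score
#' @return p-value in `[0, 1]`.
#' @export
enrichment_pvalue <- function(n, m, k, q) {
  abort_if(m <= 0 || q <= 0 || k < 0, "invalid hypergeometric configuration")
  abort_if(m > q || k > q, "sample or successes exceed the universe")
  abort_if(n > min(m, k), "impossible configuration: n > min(m, k)")
  stats::phyper(n - 1, k, q - k, m, lower.tail = FALSE)
}

#' GO-term enrichment of a sample OG set against a population OG set
#'
#' Per repeat, one gene is drawn per OG in both sets; per GO term the counts
#' `n` (sample genes with the term), `m` (sample size), `k` (population genes
#' with the term) and `q` (population size) are tabulated; the fold score is
#' `(n/m)/(k/q)` and the p-value a one-sided hypergeometric test. By default
#' the test's background universe is the union of the sampled sample and
#' population genes (`background = "union"`), since the two OG sets are
#' disjoint; `background = "population"` restricts it to the population draw.
#' Terms absent from the population (`k = 0`) get score `NA` but a valid
#' p-value.
#'
#' @param sample_ogs,population_ogs character vectors of OG ids.
#' @param og_to_genes named list: OG -> genes.
#' @param gene_to_go data.frame with columns `gene`, `go` (one row per
#'   annotation), as read by [read_gene2go_tsv()].
#' @param repeats number of resampling repeats (default 10).
#' @param min_overlap minimum `n` for a term to count as significant
#'   (default 3).
#' @param alpha p-value cut for significance (default 0.01; no
#'   multiple-testing correction, matching the raw cut).
#' @param seed RNG seed; repeat `r` uses `seed + r - 1`.
#' @param background `"union"` or `"population"`.
#' @return data.frame with one row per (GO term, repeat): `go_term`,
#'   `repeat_index`, `n`, `m`, `k`, `q`, `score`, `p_value`, `significant`.
#'   Warns when no term ever reaches `min_overlap`.
#' @export
go_enrichment <- function(sample_ogs, population_ogs, og_to_genes, gene_to_go,
                          repeats = 10, min_overlap = 3, alpha = 0.01,
                          seed = 1L, background = c("union", "population")) {
  background <- match.arg(background)
  abort_if(length(sample_ogs) == 0 || length(population_ogs) == 0,
           "sample and population OG sets must be nonempty")
  go_of <- split(as.character(gene_to_go$go), as.character(gene_to_go$gene))

  one_repeat <- function(r) {
    sg <- sample_genes(sample_ogs, og_to_genes, seed = seed + r - 1)
    pg <- sample_genes(population_ogs, og_to_genes, seed = seed + r - 1 + repeats)
    m <- length(sg)
    q <- length(pg)
    sample_terms <- table(unlist(go_of[sg], use.names = FALSE))
    pop_terms <- table(unlist(go_of[pg], use.names = FALSE))
    terms <- sort(union(names(sample_terms), names(pop_terms)))
    if (length(terms) == 0) return(NULL)
    n <- as.integer(sample_terms[terms]); n[is.na(n)] <- 0L
    k <- as.integer(pop_terms[terms]);    k[is.na(k)] <- 0L
    if (background == "union") {
      K <- n + k
      Q <- m + q
    } else {
      K <- k
      Q <- q
    }
    score <- ifelse(k > 0, (n / m) / (k / q), NA_real_)
    # under a population-only background a sample-exclusive term has K < n;
    # the test is then undefined and the row is flagged with p = NA
    p <- vapply(seq_along(terms), function(i) {
      if (n[i] > min(m, K[i])) NA_real_ else enrichment_pvalue(n[i], m, K[i], Q)
    }, numeric(1))
    data.frame(go_term = terms, repeat_index = r, n = n, m = m, k = k, q = q,
               score = score, p_value = p,
               significant = n >= min_overlap & !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(repeats), one_repeat))
  if (is.null(out) || !any(out$n >= min_overlap)) {
    warning(sprintf("no GO term reached the minimum overlap of %d", min_overlap),
            call. = FALSE)
  }
  out
}
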