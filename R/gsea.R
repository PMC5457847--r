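# signal-to-noise metric with the conventional sd floor:
# each group sd is floored at max(0.2 * |group mean|, 0.2)
s2n_floor <- function(s, mu) pmax(s, 0.2 * abs(mu), 0.2)

#' Rank features by the signal-to-noise metric
#'
#' The ranking metric of phenotype-label GSEA:
#' `(mean_case - mean_control) / (sd_case + sd_control)`, with each group sd
#' floored at `max(0.2 * |group mean|, 0.2)`. Features are returned in
#' descending metric order; ties are broken lexicographically by feature id
#' so the ranking is strict and reproducible.
#'
#' @param study An [expression_study] with at least 3 samples per group.
#' @return A tibble (class `ranked_list`) with columns `feature`, `metric`,
#'   ordered descending.
#' @export
rank_by_signal_to_noise <- function(study) {
  gs <- group_stats(study)
  if (gs$n1 < 3 || gs$n2 < 3) {
    stop("signal-to-noise ranking needs >=3 samples per group", call. = FALSE)
  }
  s1 <- s2n_floor(sqrt(gs$v1), gs$m1)
  s2 <- s2n_floor(sqrt(gs$v2), gs$m2)
  metric <- (gs$m1 - gs$m2) / (s1 + s2)
  feats <- rownames(study$values)
  o <- order(-metric, feats)
  out <- tibble::tibble(feature = feats[o], metric = unname(metric[o]))
  structure(out, class = c("ranked_list", class(out)))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing by
#' `|metric|^weight / sum_hits |metric|^weight` at gene-set members (hits)
#' and decrementing by `1/(N - n_hits)` at non-members. The enrichment score
#' is the walk value of maximal absolute deviation, sign kept; a magnitude
#' tie between the positive and negative extremum resolves to the positive
#' one. The leading edge is the set members at or before the
#' walk maximum for positive scores, and at or after the walk minimum for
#' negative scores. If every hit weight is zero the hit increments fall back
#' to uniform.
#'
#' @param ranked A `ranked_list` from [rank_by_signal_to_noise()], or any
#'   tibble with `feature` and `metric` columns in rank order.
#' @param gene_set Character vector of member genes.
#' @param weight Weighting exponent; 1 (the conventional default) weights
#'   hits by their metric, 0 gives the classical two-sample KS walk.
#' @return An object of class `gsea_es`: list with `es`, `walk` (numeric
#'   vector over ranked positions), `leading_edge`, `hits` (positions),
#'   `size`, or `NULL` (with a warning) when the set does not intersect the
#'   ranked universe.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  h <- ranked$feature %in% gene_set
  m <- sum(h)
  if (m == 0) {
    warning("gene set does not intersect the ranked list; skipping",
            call. = FALSE)
    return(NULL)
  }
  n <- nrow(ranked)
  w <- abs(ranked$metric)^weight * h
  sw <- sum(w)
  if (sw == 0) {
    w[h] <- 1
    sw <- m
  }
  dec <- if (n > m) 1 / (n - m) else 0
  steps <- w / sw
  steps[!h] <- -dec
  walk <- cumsum(steps)
  top <- max(walk)
  bot <- min(walk)
  # magnitude ties between the positive and negative extremum resolve to
  # the positive one (tolerance guards against summation-order noise)
  use_top <- top + bot >= -1e-12
  i <- if (use_top) which.max(walk) else which.min(walk)
  es <- walk[i]
  leading <- if (es > 0) {
    ranked$feature[h & seq_len(n) <= i]
  } else if (es < 0) {
    ranked$feature[h & seq_len(n) >= i]
  } else character()
  structure(list(es = es, walk = walk, leading_edge = leading,
                 hits = which(h), size = m, weight = weight),
            class = "gsea_es")
}

#' @export
print.gsea_es <- function(x, ...) {
  cat(sprintf("<gsea_es> ES = %.4f, %d hits, %d leading-edge genes\n",
              x$es, x$size, length(x$leading_edge)))
  invisible(x)
}

#' @export
tidy.gsea_es <- function(x, ...) {
  tibble::tibble(position = seq_along(x$walk), walk = x$walk,
                 hit = seq_along(x$walk) %in% x$hits)
}

#' @export
glance.gsea_es <- function(x, ...) {
  tibble::tibble(es = x$es, size = x$size,
                 n_leading = length(x$leading_edge), weight = x$weight)
}

# O(m) enrichment score from hit positions in a ranked list of length n.
# pos: positions (any order); w: matching |metric|^weight values.
es_from_positions <- function(pos, w, n) {
  m <- length(pos)
  o <- order(pos)
  pos <- pos[o]
  w <- w[o]
  sw <- sum(w)
  p_cum <- if (sw == 0) seq_len(m) / m else cumsum(w) / sw
  dec <- if (n > m) 1 / (n - m) else 0
  gap <- (pos - seq_len(m)) * dec
  top <- p_cum - gap                 # walk value at each hit
  bot <- c(0, p_cum[-m]) - gap       # walk value just before each hit
  mx <- max(top)
  mn <- min(bot)
  if (mx + mn >= -1e-12) mx else mn  # ties resolve positive, as in the walk
}

# signal-to-noise metric matrix for a set of case-assignment columns
# X: features x samples; case_mat: logical samples x n_perm
s2n_matrix <- function(X, case_mat) {
  n1 <- colSums(case_mat)[1]
  n2 <- nrow(case_mat) - n1
  C <- matrix(as.numeric(case_mat), nrow = nrow(case_mat))
  X2 <- X^2
  m1 <- (X %*% C) / n1
  m2 <- (X %*% (1 - C)) / n2
  v1 <- ((X2 %*% C) / n1 - m1^2) * n1 / (n1 - 1)
  v2 <- ((X2 %*% (1 - C)) / n2 - m2^2) * n2 / (n2 - 1)
  v1[v1 < 0] <- 0
  v2[v2 < 0] <- 0
  s1 <- s2n_floor(sqrt(v1), m1)
  s2 <- s2n_floor(sqrt(v2), m2)
  (m1 - m2) / (s1 + s2)
}

#' Run GSEA over a pathway collection with phenotype permutations
#'
#' For each pathway: observed enrichment score and leading edge from the
#' signal-to-noise ranking of the study, and a nominal phenotype-permutation
#' p value. Group labels are permuted `n_perm` times (shared across
#' pathways), the list is re-ranked and re-scored each time, and
#' `p = (1 + #{permutations with |ES| >= |ES_obs|}) / (1 + n_perm)`: a
#' two-sided rank p on the score magnitude, exactly uniform for a null
#' pathway and bounded below by `1/(n_perm + 1)`.
#'
#' @param study An [expression_study].
#' @param pathways A `gene_set_collection` (or named list).
#' @param weight Hit-weighting exponent (default 1).
#' @param n_perm Number of label permutations (default 1000, minimum 10).
#' @param seed Integer seed; results are deterministic in it.
#' @param keep_walks Keep the observed running-sum walk per pathway
#'   (list-column `walk`)? Default `FALSE`.
#' @return A tibble of class `gsea_scan`: `pathway`, `size`, `es`, `p`,
#'   `n_leading`, `leading_edge` (list-column), `n_perm`, plus `walk` when
#'   requested. Pathways that do not intersect the study's features are
#'   skipped with a warning.
#' @export
gsea_scan <- function(study, pathways, weight = 1, n_perm = 1000, seed = 1,
                      keep_walks = FALSE) {
  if (n_perm < 10) stop("n_perm must be at least 10", call. = FALSE)
  # fixed row order = feature-id order, so row index breaks metric ties
  X <- study$values[order(rownames(study$values)), , drop = FALSE]
  feats <- rownames(X)
  n <- nrow(X)
  labels <- study$labels
  n1 <- sum(labels == "case")
  ns <- length(labels)
  if (choose(ns, n1) < n_perm) {
    message("fewer distinct label permutations (", choose(ns, n1),
            ") than n_perm; permutations are sampled with replacement")
  }

  obs_case <- labels == "case"
  obs_metric <- drop(s2n_matrix(X, matrix(obs_case, ncol = 1)))
  obs_ord <- order(-obs_metric, seq_len(n))
  ranked <- tibble::tibble(feature = feats[obs_ord],
                           metric = obs_metric[obs_ord])

  sets <- as.list(pathways)
  hit_idx <- lapply(sets, function(s) which(feats %in% s))
  keep <- lengths(hit_idx) > 0
  if (any(!keep)) {
    warning(sum(!keep), " pathway(s) do not intersect the study; skipped",
            call. = FALSE)
  }
  sets <- sets[keep]
  hit_idx <- hit_idx[keep]

  obs <- lapply(sets, function(s) enrichment_score(ranked, s, weight))

  set.seed(seed)
  case_mat <- vapply(seq_len(n_perm), function(j) {
    idx <- sample.int(ns, n1)
    seq_len(ns) %in% idx
  }, logical(ns))
  M <- s2n_matrix(X, case_mat)
  # rank of each feature (row) within each permutation's ordering
  RK <- apply(M, 2, function(v) {
    rk <- integer(n)
    rk[order(-v, seq_len(n))] <- seq_len(n)
    rk
  })
  AW <- abs(M)^weight

  p_vals <- vapply(seq_along(sets), function(s) {
    idx <- hit_idx[[s]]
    es_obs <- obs[[s]]$es
    es_perm <- vapply(seq_len(n_perm), function(j) {
      es_from_positions(RK[idx, j], AW[idx, j], n)
    }, numeric(1))
    # |ES| is exchangeable between the observed labeling and its
    # permutations under the null, so this p is exactly uniform on
    # {1/(n_perm+1), ..., 1} for a null pathway
    (1 + sum(abs(es_perm) >= abs(es_obs))) / (1 + n_perm)
  }, numeric(1))

  out <- tibble::tibble(
    pathway = names(sets),
    size = lengths(hit_idx),
    es = vapply(obs, `[[`, numeric(1), "es"),
    p = p_vals,
    n_leading = vapply(obs, function(o) length(o$leading_edge), integer(1)),
    leading_edge = lapply(obs, `[[`, "leading_edge"),
    n_perm = n_perm
  )
  if (keep_walks) out$walk <- lapply(obs, `[[`, "walk")
  structure(out, class = c("gsea_scan", class(out)))
}

#' Nominal permutation p value for one pathway
#'
#' Convenience wrapper around [gsea_scan()] for a single gene set.
#'
#' @inheritParams gsea_scan
#' @param pathway Character vector of member genes.
#' @return The nominal p value (numeric scalar).
#' @export
gsea_permutation_p <- function(study, pathway, n_perm = 1000, seed = 1,
                               weight = 1) {
  res <- gsea_scan(study, list(set = pathway), weight = weight,
                   n_perm = n_perm, seed = seed)
  if (!nrow(res)) stop("pathway does not intersect the study", call. = FALSE)
  res$p[[1]]
}

#' Consensus risk-pathway selection across datasets
#'
#' A pathway is flagged a risk pathway when its nominal enrichment p value
#' is below `p_threshold` in strictly more than `dataset_fraction` of the
#' datasets. A pathway absent from some dataset's results counts as not
#' significant there.
#'
#' @param results Named list of `gsea_scan` tibbles, one per dataset.
#' @param p_threshold Enrichment p cutoff (default 0.1).
#' @param dataset_fraction Fraction that must be exceeded (strictly) for the
#'   risk flag (default 0.5).
#' @return Tibble of class `sig_pathway_set`: `pathway`, one `p_<dataset>`
#'   column per dataset, `n_sig`, `n_datasets`, `risk`.
#' @export
select_sig_pathways <- function(results, p_threshold = 0.1,
                                dataset_fraction = 0.5) {
  stopifnot(is.list(results), length(results) >= 1)
  nm <- names(results)
  if (is.null(nm) || any(!nzchar(nm))) nm <- sprintf("dataset%d", seq_along(results))
  all_paths <- sort(unique(unlist(lapply(results, function(r) r$pathway))))
  p_mat <- vapply(results, function(r) {
    r$p[match(all_paths, r$pathway)]
  }, numeric(length(all_paths)))
  p_mat <- matrix(p_mat, ncol = length(results))
  n_sig <- rowSums(p_mat < p_threshold, na.rm = TRUE)
  out <- tibble::tibble(pathway = all_paths)
  for (j in seq_along(results)) out[[paste0("p_", nm[j])]] <- p_mat[, j]
  out$n_sig <- as.integer(n_sig)
  out$n_datasets <- length(results)
  out$risk <- n_sig / length(results) > dataset_fraction
  structure(out, class = c("sig_pathway_set", class(out)))
}

#' Pool leading-edge (core) genes of the risk pathways
#'
#' Core genes "contribute most" to an enriched pathway: they are the
#' leading-edge members of its GSEA walk. This helper takes the union of
#' leading edges of the flagged risk pathways across all datasets.
#'
#' @param results Named list of `gsea_scan` tibbles.
#' @param sig_pathways A `sig_pathway_set` from [select_sig_pathways()], or
#'   a character vector of pathway names.
#' @return Character vector of core genes.
#' @export
core_genes <- function(results, sig_pathways) {
  if (is.data.frame(sig_pathways)) {
    sig_pathways <- sig_pathways$pathway[sig_pathways$risk]
  }
  le <- unlist(lapply(results, function(r) {
    r$leading_edge[r$pathway %in% sig_pathways]
  }))
  sort(unique(unlist(le)))
}
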