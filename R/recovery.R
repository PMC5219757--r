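#' Score recovery of planted modules by a fitted model
#'
#' Inferred module rows (normalized to distributions) are matched
#' one-to-one to the planted distributions by maximizing total cosine
#' similarity (Hungarian assignment on the padded similarity matrix).
#' Token-level accuracy is computed under that matching at the
#' (region, factor) level: within each cell, the overlap between the
#' planted module multiset and the (mapped) inferred module multiset.
#'
#' @param truth the `truth` element of a [simulate_binding_data()] output
#'   (needs `phi` and `sites`).
#' @param module_tf inferred module-TF matrix from [extract_outputs()].
#' @param assignments inferred assignment table; region ids must
#'   correspond positionally to the planted regions (guaranteed by the
#'   generator's anchor-spacing spacing, and checked here via site
#'   counts).
#' @return list with `mean_cosine` (over planted modules; unmatched
#'   planted modules score 0), `k_inferred`, `k_true`, `k_diff`,
#'   `token_accuracy`, and `matching` (inferred -> planted module index,
#'   NA if unmatched).
#' @export
score_recovery <- function(truth, module_tf, assignments) {
  phi <- truth$phi
  k_true <- nrow(phi)
  k_inf <- nrow(module_tf)
  # align the fitted vocabulary to the planted one; factors the fit never
  # saw contribute zero columns
  aligned <- matrix(0, k_inf, ncol(phi),
                    dimnames = list(rownames(module_tf), colnames(phi)))
  shared <- intersect(colnames(module_tf), colnames(phi))
  aligned[, shared] <- module_tf[, shared]
  phat <- aligned / pmax(rowSums(aligned), 1)

  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  sim <- matrix(0, k_inf, k_true)
  for (i in seq_len(k_inf)) {
    for (j in seq_len(k_true)) sim[i, j] <- cosine(phat[i, ], phi[j, ])
  }

  n <- max(k_inf, k_true)
  padded <- matrix(0, n, n)
  padded[seq_len(k_inf), seq_len(k_true)] <- sim
  sol <- clue::solve_LSAP(1 - padded + 1)  # minimize cost = maximize sim
  matching <- rep(NA_integer_, k_inf)
  for (i in seq_len(k_inf)) {
    j <- sol[i]
    if (j <= k_true) matching[i] <- j
  }
  matched_cos <- vapply(seq_len(k_true), function(j) {
    i <- match(j, matching)
    if (is.na(i)) 0 else sim[i, j]
  }, 0)

  # token accuracy at (region, factor) granularity
  t_ids <- paste(truth$sites$region_index, truth$sites$factor, sep = "\r")
  reg_index <- match(assignments$region_id,
                     sort(unique(assignments$region_id)))
  a_ids <- paste(reg_index, assignments$factor, sep = "\r")
  if (nrow(assignments) != nrow(truth$sites)) {
    stop("assignment table and planted sites differ in size; region ",
         "correspondence is broken")
  }
  mapped <- matching[assignments$module]
  total <- nrow(truth$sites)
  agree <- 0
  t_split <- split(truth$sites$module, t_ids)
  a_split <- split(mapped, a_ids)
  common <- intersect(names(t_split), names(a_split))
  for (id in common) {
    tt <- tabulate(t_split[[id]], nbins = k_true)
    aa <- tabulate(a_split[[id]][!is.na(a_split[[id]])], nbins = k_true)
    agree <- agree + sum(pmin(tt, aa))
  }

  list(mean_cosine = mean(matched_cos), k_inferred = k_inf,
       k_true = k_true, k_diff = k_inf - k_true,
       token_accuracy = agree / total, matching = matching,
       similarity = sim)
}
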