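#' Simulate negative-binomial RNA-seq counts with planted fold changes
#'
#' Draws per-gene baseline expression levels, plants a log2 fold change on a
#' chosen subset of genes in the treated condition, perturbs per-sample
#' library sizes, and samples counts from a negative-binomial model
#' (`var = mu + dispersion * mu^2`; `dispersion = 0` reduces to Poisson).
#' Replicated libraries are generated per condition — triplicates by
#' default, the standard minimal replicated RNA-seq design.
#'
#' @param annotation a `gene_annotation`; one count row per gene.
#' @param n_de number of genes carrying the planted fold (0 for pure null).
#' @param log2_fold planted log2 fold change in the treated condition; must
#'   be nonzero when `n_de > 0`.
#' @param dispersion negative-binomial dispersion alpha (>= 0).
#' @param depth expected total reads per library before library-size jitter.
#' @param seed integer seed (substream-expanded).
#' @param n_reps replicate libraries per condition.
#' @param libsize_jitter half-width of the uniform per-sample library-size
#'   factor perturbation around 1.
#' @return list with integer matrices `vehicle` and `treated` (genes x
#'   replicates) and `truth`, a list recording `de_genes` (gene_id,
#'   log2_fold), per-sample `size_factors`, and the per-gene mean parameters
#'   `mu_vehicle`, `mu_treated`.
#' @export
generate_counts <- function(annotation, n_de, log2_fold, dispersion,
                            depth = 1e6, seed = 1L, n_reps = 3L,
                            libsize_jitter = 0.1) {
  stopifnot(inherits(annotation, "gene_annotation"))
  n_genes <- nrow(annotation$genes)
  assert_scalar_number(n_de, "n_de", min = 0, max = n_genes)
  assert_scalar_number(dispersion, "dispersion", min = 0)
  assert_scalar_number(depth, "depth", min = 0, strict_min = TRUE)
  if (n_de > 0 && (!is.finite(log2_fold) || log2_fold == 0))
    stop("planted fold of magnitude 0 rejected")
  set.seed(substream_seed(seed, "counts"))

  gids <- annotation$genes$gene_id
  base_w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  mu_vehicle <- depth * base_w / sum(base_w)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  fold <- rep(1, n_genes)
  fold[de_idx] <- 2^log2_fold
  mu_treated <- mu_vehicle * fold

  sf <- runif(2L * n_reps, 1 - libsize_jitter, 1 + libsize_jitter)
  names(sf) <- c(paste0("vehicle_", seq_len(n_reps)),
                 paste0("treated_", seq_len(n_reps)))

  draw <- function(mu) {
    if (dispersion == 0) rpois(length(mu), lambda = mu)
    else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  veh <- sapply(seq_len(n_reps), function(j) draw(mu_vehicle * sf[j]))
  trt <- sapply(seq_len(n_reps), function(j) draw(mu_treated * sf[n_reps + j]))
  veh <- matrix(as.integer(veh), nrow = n_genes,
                dimnames = list(gids, names(sf)[seq_len(n_reps)]))
  trt <- matrix(as.integer(trt), nrow = n_genes,
                dimnames = list(gids, names(sf)[n_reps + seq_len(n_reps)]))

  truth <- list(
    de_genes = data.frame(gene_id = gids[de_idx],
                          log2_fold = rep(log2_fold, length(de_idx)),
                          stringsAsFactors = FALSE),
    size_factors = sf,
    mu_vehicle = setNames(mu_vehicle, gids),
    mu_treated = setNames(mu_treated, gids)
  )
  list(vehicle = veh, treated = trt, truth = truth)
}
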