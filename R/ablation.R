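#' Ablation harness: which regularizer does what?
#'
#' Runs the reconstruction four times per seed on bit-identical noisy
#' inputs - no regularizer ("cs"), TV only ("cs+tv"), self-similarity only
#' ("cs+nls"), and both ("cs+tv+nls") - and reports PSNR and SSIM against
#' the clean image for each variant, plus per-variant means.
#'
#' @param image the clean [CSImage-class].
#' @param noise a [NoiseSpec-class] describing the corruption.
#' @param config a [SolverConfig-class]; only its `enableTV`/`enableNLS`
#'   flags are varied.
#' @param seeds integer vector of noise seeds.
#' @param operator a [SensingOperator-class] or NULL for identity.
#' @return a data.frame with columns `variant`, `seed`, `psnr_db`, `ssim`;
#'   the per-variant means are attached as attribute `"means"`.
#' @examples
#' ph <- makePhantom(64, 64, seed = 1)
#' cfg <- solverConfig(sigma = 20, maxOuter = 5,
#'                     nls = nlsParams(blockSize = 4, groupSize = 4,
#'                                     searchWindow = 11))
#' tab <- runAblation(ph, noiseSpec("awgn", sigma = 20), cfg, seeds = 0)
#' @export
runAblation <- function(image, noise, config, seeds = 0:4, operator = NULL) {
  stopifnot(is(image, "CSImage"), is(noise, "NoiseSpec"))
  variants <- list("cs" = c(FALSE, FALSE), "cs+tv" = c(TRUE, FALSE),
                   "cs+nls" = c(FALSE, TRUE), "cs+tv+nls" = c(TRUE, TRUE))
  rows <- list()
  for (seed in seeds) {
    noisy <- applyNoise(image, noise, seed = seed)
    for (vn in names(variants)) {
      cfg <- config
      cfg@enableTV <- variants[[vn]][1]
      cfg@enableNLS <- variants[[vn]][2]
      cfg@seed <- as.integer(seed)
      res <- tvnlsReconstruct(noisy, operator, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, seed = seed,
        psnr_db = as.numeric(imagePSNR(image, res$image)),
        ssim = imageSSIM(image, res$image))
    }
  }
  tab <- do.call(rbind, rows)
  means <- stats::aggregate(cbind(psnr_db, ssim) ~ variant, tab, mean)
  attr(tab, "means") <- means[match(names(variants), means$variant), ]
  tab
}
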