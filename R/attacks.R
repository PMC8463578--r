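# Fast gradient sign method (FGSM) adversarial images against the reference
# ANN and against the SNN (input gradients accumulated over all time-steps
# via surrogate BPTT, taken w.r.t. the analog image that parameterizes the
# Poisson rates; raw gradients are summed over t before the single sign).

#' FGSM adversarial image
#'
#' Perturbs the image by `epsilon * sign(g)` in normalized `[0, 1]` pixel
#' units and clips to range, where `g` is the gradient of the cross-entropy
#' loss at the true label with respect to the input. For `mode = "ann"` the
#' gradient is exact; for `mode = "snn"` it is the surrogate-BPTT input
#' gradient summed over all time-steps of a Poisson-coded forward run.
#'
#' @param model List with `kind` (`"ann"` or `"snn"`), `config`, `weights`.
#' @param image An [image_tensor()] in `[0, 255]`.
#' @param label Ground-truth class index (1-based).
#' @param epsilon Perturbation budget in normalized pixel units (e.g.
#'   `4/255`), in `[0, 1]`.
#' @param seed Seed for the Poisson coding in SNN mode.
#' @return Adversarial image array (same shape, values in `[0, 255]`), with
#'   the exact float perturbation (normalized units) attached as attribute
#'   `"perturbation"`.
#' @export
fgsm <- function(model, image, label, epsilon, seed = NULL) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1) {
    stopf("epsilon must be a single value in [0, 1]")
  }
  image <- image_tensor(unclass(image))
  x <- as.numeric(image) / 255
  d <- dim(image)
  if (model$kind == "ann") {
    xb <- array(x, c(d, 1L))
    fwd <- ann_forward(model$config, model$weights, xb, keep = TRUE)
    lg <- ce_loss_grad(fwd$logits, label)
    g <- ann_backward(model$config, model$weights, fwd, lg$dlogits,
                      input_grad = TRUE)$input_grad
  } else if (model$kind == "snn") {
    raster <- poisson_encode(image, model$config$timesteps, seed = seed)
    raster <- array(raster, c(dim(raster), 1L))
    fwd <- snn_forward(model$config, model$weights, raster, keep = TRUE)
    lg <- ce_loss_grad(fwd$potentials, label)
    g <- snn_backward(model$config, model$weights, fwd, lg$dlogits,
                      input_grad = TRUE)$input_grad
  } else {
    stopf("model kind must be 'ann' or 'snn'")
  }
  pert <- epsilon * sign(as.numeric(g))
  x_adv <- clamp(x + pert, 0, 1)
  out <- array(x_adv * 255, d)
  attr(out, "perturbation") <- array(pert, d)
  out
}
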