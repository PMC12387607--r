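# Desk-scale end-to-end training runs, computed once per test session and
# shared by several tests.  One synthetic dataset (200 training patches, 50
# held-out), five training seeds; for every seed the pooled nuclei-level
# Dice of the single-pass prediction and of the 5-view averaging ensemble
# over the held-out set.

pipeline_cache <- new.env(parent = emptyenv())

pipeline_runs <- function() {
  if (!is.null(pipeline_cache$runs)) return(pipeline_cache$runs)
  ds <- generate_dataset(synth_spec(), n = 250,
                         split = c(train = 0.8, test = 0.2, val = 0),
                         seed = 11)
  tr <- split_samples(ds, "train")
  te <- split_samples(ds, "test")
  runs <- lapply(1:5, function(s) {
    fit <- fit_dpnet(tr, epochs = 6, batch_size = 16, seed = s)
    cs <- ca <- list(tp = 0, fp = 0, fn = 0, tn = 0)
    acc <- function(tot, cc) {
      tot$tp <- tot$tp + cc$tp; tot$fp <- tot$fp + cc$fp
      tot$fn <- tot$fn + cc$fn; tot$tn <- tot$tn + cc$tn
      tot
    }
    for (sm in te) {
      truth <- binarize_nuclei(sm$truth)
      cm1 <- predict(fit, sm$image, tta = "none")
      cma <- run_tta_inference(fit, sm$image, mode = "average", views = 5)
      cs <- acc(cs, confusion_from_maps(binarize_nuclei(cm1), truth))
      ca <- acc(ca, confusion_from_maps(binarize_nuclei(cma), truth))
    }
    dice <- function(x) 2 * x$tp / (2 * x$tp + x$fp + x$fn)
    list(seed = s, history = fit$history,
         dice_single = dice(cs), dice_average = dice(ca))
  })
  pipeline_cache$runs <- runs
  runs
}
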