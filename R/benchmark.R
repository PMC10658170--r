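#' Desk-scale synthetic benchmarks
#'
#' The package's standard benchmark recipes on the synthetic shell
#' family, sized for a single CPU: 80 shells (60 train / 20 test) at
#' 32^3, a channel list of `[4, 4, 8, 8, 16, 16, 32]`, 8 epochs of Adam
#' at learning rate 3e-3.  For completion, predictions are united with
#' the defective input (the completion target contains the input by
#' definition); super-resolution predictions never are, since misplaced
#' input points must be prunable.  All randomness derives from `seed`.
#'
#' These benchmarks characterize the engine on synthetic data; they do
#' not reproduce published results on real MRI/CT skulls (see
#' [reproducibility_notes()]).
#'
#' @param seed integer master seed (dataset seeds and training seeds are
#'   derived from it).
#' @param n number of shells (default 80, split 60/20).
#' @param epochs training epochs.
#' @param ch channel list of the benchmark network.
#' @param lr Adam learning rate.
#' @return A list of summary numbers: for completion `test_dsc`,
#'   `input_dsc`, `test_re_percent`, `implant_dsc`; for super-resolution
#'   `test_dsc` and `interp_dsc` (the trilinear up-scaling baseline);
#'   both include `n_train`, `n_test` and the fitted checkpoint.
#' @export
run_completion_benchmark <- function(seed = 1L, n = 80L, epochs = 8L,
                                     ch = c(4L, 4L, 8L, 8L, 16L, 16L, 32L),
                                     lr = 3e-3) {
  ds <- make_dataset(n, resolutions = 32L, task = "completion",
                     seed = seed + 10L)
  sp <- dataset_splits(ds)
  cfg <- train_config("completion", ch = ch, epochs = epochs, lr = lr,
                      seed = seed, union_input = TRUE)
  ck <- train_completion(sp$train, cfg)
  per <- vapply(sp$test, function(s) {
    p <- predict_grid(ck, s$defective)
    imp <- extract_implant(p, s$defective, cleanup = FALSE)
    c(dsc(p, s$complete),
      dsc(s$defective, s$complete),
      reconstruction_error(p, s$complete)$re_percent,
      dsc(imp, s$implant))
  }, numeric(4))
  list(test_dsc = mean(per[1, ]), input_dsc = mean(per[2, ]),
       test_re_percent = mean(per[3, ]), implant_dsc = mean(per[4, ]),
       n_train = length(sp$train), n_test = length(sp$test),
       checkpoint = ck)
}

#' @rdname run_completion_benchmark
#' @export
run_superres_benchmark <- function(seed = 1L, n = 80L, epochs = 8L,
                                   ch = c(4L, 4L, 8L, 8L, 16L, 16L, 32L),
                                   lr = 3e-3) {
  ds <- make_dataset(n, resolutions = c(16L, 32L), task = "superres",
                     seed = seed + 20L)
  sp <- dataset_splits(ds)
  cfg <- train_config("superres", ch = ch, epochs = epochs, lr = lr,
                      seed = seed)
  ck <- train_superres(sp$train, cfg)
  per <- vapply(sp$test, function(s) {
    c(dsc(predict_grid(ck, s$input), s$target),
      dsc(s$input, s$target))
  }, numeric(2))
  list(test_dsc = mean(per[1, ]), interp_dsc = mean(per[2, ]),
       n_train = length(sp$train), n_test = length(sp$test),
       checkpoint = ck)
}
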