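# A single synthetic training set and classifier shared across test files
# (building them once keeps the suite fast; seeds are fixed).
.shared <- new.env()

shared_training_set <- function() {
  if (is.null(.shared$ts))
    .shared$ts <- generate_training_set(n_per_class = 150L, seed = 5L)
  .shared$ts
}

shared_model <- function() {
  if (is.null(.shared$model))
    .shared$model <- train_classifier(shared_training_set(), seed = 1L)
  .shared$model
}

# Small solid-colour RGB array helper.
flat_rgb <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}
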