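# Phantoms are moderately expensive to render, so tests share a memoised cache.
.fixture_cache <- new.env(parent = emptyenv())

fixture_phantom <- function(class_label, image_size = 128, seed = 1, ...) {
  key <- paste(class_label, image_size, seed,
               paste(unlist(list(...)), collapse = "_"), sep = "_")
  if (!exists(key, .fixture_cache)) {
    assign(key, generate_phantom(phantom_spec(class_label,
                                              image_size = image_size,
                                              seed = seed, ...)),
           .fixture_cache)
  }
  get(key, .fixture_cache)
}

# wrap a phantom's ground-truth labels as a segmentation map
gt_segmentation <- function(ph) {
  structure(list(labels = ph$labels, k = 4L,
                 annotations = c("HP", "SHG", "WD", "RC")),
            class = "segmentation_map")
}

random_cube <- function(h, w, c = 25, seed = 1) {
  withr::with_seed(seed,
    spectral_image(array(sample(0:255, h * w * c, replace = TRUE), c(h, w, c))))
}
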