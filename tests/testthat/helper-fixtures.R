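# Shared helpers: tiny network configurations, labelled feature maps and
# parameter surgery used across the unit tests.

# a feature map whose channel c is constant at value c (labelled channels)
labelled_map <- function(H = 2L, W = 2L, C = 4L) {
  array(rep(seq_len(C), each = H * W), c(H, W, C))
}

random_map <- function(H, W, C, seed = 1L) {
  set.seed(seed)
  array(rnorm(H * W * C), c(H, W, C))
}

tiny_config <- function(...) {
  network_config(input_size = 8L, stage_channels = c(4L),
                 num_classes = 3L, hidden_units = 6L, ...)
}

# set every convolution weight (and gate weight/bias) in a block to zero,
# leaving batch-norm at its identity initialization
zero_block <- function(block) {
  for (sn in names(block$sub)) {
    block$sub[[sn]]$params$W <- block$sub[[sn]]$params$W * 0
    if (!is.null(block$sub[[sn]]$params$b))
      block$sub[[sn]]$params$b <- block$sub[[sn]]$params$b * 0
  }
  block
}

# small in-memory graded patch set (cached per session; generation is the
# slow part of the data-path tests)
small_patch_set <- local({
  cache <- NULL
  function(per_class = 6L, out_size = 32L, seed = 77L) {
    key <- paste(per_class, out_size, seed)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    ps <- generate_patch_set(
      synthetic_spec(per_class = rep(per_class, 5L), size = 96L,
                     seed = seed),
      out_size = out_size)
    attr(ps, "key") <- key
    cache <<- ps
    ps
  }
})

# folder-per-class PNG tree with tiny images, for pipeline tests
make_image_tree <- function(root, classes = paste0("Grade", 0:4),
                            per_class = 2L, size = 8L, seed = 3L) {
  set.seed(seed)
  for (cl in classes) {
    d <- file.path(root, cl)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(per_class))
      png::writePNG(array(runif(size * size * 3), c(size, size, 3L)),
                    file.path(d, sprintf("img%02d.png", i)))
  }
  root
}
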