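# Shared fixtures built in code. The gallery render is cached per test run.

.gallery_cache <- new.env(parent = emptyenv())

get_gallery <- function() {
  if (is.null(.gallery_cache$gal)) .gallery_cache$gal <- fixture_gallery(seed = 1)
  .gallery_cache$gal
}

# 2D Gaussian spot, peak `amp` at `center`, standard deviation `sigma`.
gaussian_spot <- function(shape, center, sigma, amp = 100, background = 0) {
  outer(seq_len(shape[1]), seq_len(shape[2]), function(r, cc) {
    background + amp * exp(-((r - center[1])^2 + (cc - center[2])^2) / (2 * sigma^2))
  })
}

# Horizontal bright band of full width `w` centred on `row0`.
band_image <- function(shape, row0, w, intensity = 300, background = 0) {
  img <- matrix(background, shape[1], shape[2])
  half <- (w - 1) / 2
  img[(row0 - floor(half)):(row0 + ceiling(half)), ] <- intensity
  img
}

# Standard dendrite analysis chain used by several test files.
analyse_dendrite <- function(fx, start, end, filter_size = 5, sigma = 2) {
  f <- get_frame(fx$stack, 1, 1)
  bm <- binarize(f, filter_size, "mean")
  p <- shortest_path(build_cost_field(bm), start, end)
  e <- detect_edges(f, sigma, filter_size)
  prof <- compute_profile(p, e)
  seg <- build_mask(p, prof, dim(f), fx$stack)
  list(frame = f, path = p, edges = e, profile = prof, seg = seg)
}
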