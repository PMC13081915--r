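#' Oversample images containing rare-class instances
#'
#' Every image holding at least one rare-category instance is
#' duplicated so that it appears `k` times in the bundle (original plus
#' `k - 1` copies), where `k` is the [duplication_factor()] computed
#' from the majority-class instance count `N_maj` (instances of the
#' single most frequent category), the total rare instance count
#' `N_rare`, and the target ratio `r`. Copies receive fresh image and
#' annotation ids (sequential from the current maxima) so the bundle
#' stays COCO-consistent; images without rare instances and all pixel
#' content are untouched.
#'
#' @param bundle A `scope_bundle`.
#' @param rare Rare category names (default: the bundle's rare flags).
#' @param ratio Target ratio `r` (default 0.5).
#' @return The oversampled bundle, with `k` recorded in provenance and
#'   as attribute `duplication_factor`.
#' @export
oversample_rare <- function(bundle, rare = NULL, ratio = 0.5) {
  rare <- rare %||% rare_names(bundle$categories)
  counts <- class_counts(bundle)
  n_rare <- sum(counts[rare])
  if (n_rare == 0) stop("no rare-class instances in the bundle")
  n_maj <- max(counts)
  k <- duplication_factor(n_maj, n_rare, ratio)
  if (k > 1L) {
    has_rare <- vapply(bundle$images, function(img) {
      any(img$annotations$category %in% rare)
    }, TRUE)
    ann <- bundle_annotations(bundle)
    next_img <- max(vapply(bundle$images, `[[`, 1L, "image_id")) + 1L
    next_ann <- if (nrow(ann)) max(ann$id) + 1L else 1L
    copies <- list()
    for (img in bundle$images[has_rare]) {
      for (rep_i in seq_len(k - 1L)) {
        cp <- img
        cp$image_id <- next_img
        next_img <- next_img + 1L
        if (nrow(cp$annotations)) {
          cp$annotations$id <- seq.int(next_ann,
                                       length.out = nrow(cp$annotations))
          next_ann <- next_ann + nrow(cp$annotations)
          cp$annotations$image_id <- cp$image_id
        }
        copies[[length(copies) + 1L]] <- cp
      }
    }
    bundle$images <- c(bundle$images, copies)
  }
  bundle <- log_provenance(bundle, sprintf(
    "oversample_rare: N_maj=%d N_rare=%d r=%g -> k=%d", n_maj, n_rare,
    ratio, k))
  attr(bundle, "duplication_factor") <- k
  bundle
}
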