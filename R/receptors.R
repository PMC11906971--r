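#' Construct a receptor/transporter atlas
#'
#' Regional density maps for neurotransmitter receptors and transporters
#' (e.g. 5-HT6, 5-HT1B, D2, VAChT, mGluR5, H3, norepinephrine
#' transporter), each target possibly contributed by several PET tracer
#' studies with sample-size weights.
#'
#' @param targets named list; each element is a list with fields `maps`
#'   (list of [regional_map()]s from contributing tracer studies) and
#'   `weights` (positive numeric, one per map; typically study sample
#'   sizes).
#' @return object of class `receptor_atlas`.
#' @export
receptor_atlas <- function(targets) {
  if (!length(targets) || is.null(names(targets))) {
    stop("`targets` must be a named list", call. = FALSE)
  }
  ids <- NULL
  for (nm in names(targets)) {
    t <- targets[[nm]]
    if (!length(t$maps)) stop("target ", nm, " has no maps", call. = FALSE)
    if (length(t$weights) != length(t$maps)) {
      stop("target ", nm, ": weights and maps lengths differ", call. = FALSE)
    }
    if (any(t$weights <= 0)) stop("target ", nm, ": weights must be > 0",
                                  call. = FALSE)
    for (m in t$maps) {
      if (is.null(ids)) ids <- region_ids(m)
      if (!identical(region_ids(m), ids)) {
        stop("all receptor maps must share region ids", call. = FALSE)
      }
    }
  }
  structure(list(targets = targets, region_ids = ids),
            class = "receptor_atlas")
}

#' @export
print.receptor_atlas <- function(x, ...) {
  cat("<receptor_atlas> ", length(x$targets), " targets, ",
      length(x$region_ids), " regions\n", sep = "")
  for (nm in names(x$targets)) {
    cat("  ", nm, ": ", length(x$targets[[nm]]$maps), " tracer map(s)\n",
        sep = "")
  }
  invisible(x)
}

#' @export
region_ids.receptor_atlas <- function(x) x$region_ids

#' Standardize receptor maps to one z-scored map per target
#'
#' Each contributing tracer map is z-scored across regions; targets with
#' several tracer studies are combined as a weight-proportional average
#' of the z-maps (weights are typically the studies' sample sizes).
#' Single-tracer targets are passed through z-scored.
#'
#' @param atlas a [receptor_atlas()].
#' @return named list of `regional_map`s (measure `"receptor_z"`), one
#'   per target.
#' @export
standardize_receptors <- function(atlas) {
  stopifnot(inherits(atlas, "receptor_atlas"))
  out <- list()
  for (nm in names(atlas$targets)) {
    t <- atlas$targets[[nm]]
    zmaps <- lapply(t$maps, function(m) zscore(as.numeric(m)))
    w <- t$weights / sum(t$weights)
    combined <- Reduce(`+`, Map(`*`, zmaps, w))
    out[[nm]] <- regional_map(combined, atlas$region_ids, "receptor_z")
  }
  out
}
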