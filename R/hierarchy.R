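#' Load a hierarchical parcellation lookup table
#'
#' Reads a multi-scale atlas hierarchy from a delimited text table with one
#' row per finest-scale parcel and, for every scale, an id and a name column
#' (`scale1_id`, `scale1_name`, `scale2_id`, `scale2_name`, ...). Scale 1 is
#' the finest parcellation; higher scale numbers are coarser. The table is
#' validated: parcel ids and names must be unique within each scale, every
#' finest parcel must have an ancestor at every scale, and the ancestor maps
#' must be consistent with a tree (two finest parcels sharing an ancestor at
#' scale s share ancestors at all scales coarser than s).
#'
#' @param path Path to the lookup table (TSV).
#' @return An `fcp_hierarchy` object: a list with elements
#'   * `n_scales` — number of scales,
#'   * `parcels` — list of tibbles (`id`, `name`), one per scale, in atlas order,
#'   * `ancestor` — list of integer vectors; `ancestor[[s]][i]` is the parcel id
#'     at scale `s` of finest parcel id `i` (`ancestor[[1]]` is the identity).
#' @seealso [fcp_hierarchy()] for the packaged five-scale gray-matter
#'   hierarchy, [coarsen_labels()], [node_count()].
#' @export
load_hierarchy <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  id_cols <- grep("^scale[0-9]+_id$", names(tab), value = TRUE)
  n_scales <- length(id_cols)
  if (n_scales < 1) {
    stop("hierarchy table must contain scale<k>_id / scale<k>_name columns",
         call. = FALSE)
  }
  for (s in seq_len(n_scales)) {
    idc <- paste0("scale", s, "_id")
    nmc <- paste0("scale", s, "_name")
    if (!idc %in% names(tab) || !nmc %in% names(tab)) {
      stop("hierarchy table is missing columns for scale ", s, call. = FALSE)
    }
    if (anyNA(tab[[idc]]) || anyNA(tab[[nmc]])) {
      stop("finest parcel lacking an ancestor at scale ", s, call. = FALSE)
    }
  }
  if (anyDuplicated(tab$scale1_id)) {
    stop("duplicate finest-scale parcel id", call. = FALSE)
  }

  parcels <- vector("list", n_scales)
  ancestor <- vector("list", n_scales)
  finest_ids <- as.integer(tab$scale1_id)
  if (any(finest_ids <= 0)) {
    stop("parcel ids must be positive (0 is reserved for background)",
         call. = FALSE)
  }
  for (s in seq_len(n_scales)) {
    ids <- as.integer(tab[[paste0("scale", s, "_id")]])
    nms <- as.character(tab[[paste0("scale", s, "_name")]])
    u <- !duplicated(ids)
    if (nrow(unique(data.frame(ids, nms))) != sum(u)) {
      stop("inconsistent id/name pairing at scale ", s, call. = FALSE)
    }
    if (anyDuplicated(nms[u])) {
      stop("duplicate parcel name at scale ", s, call. = FALSE)
    }
    ord <- order(ids[u])
    parcels[[s]] <- tibble::tibble(id = ids[u][ord], name = nms[u][ord])
    anc <- rep(NA_integer_, max(finest_ids))
    anc[finest_ids] <- ids
    ancestor[[s]] <- anc
  }

  h <- structure(
    list(n_scales = n_scales, parcels = parcels, ancestor = ancestor),
    class = "fcp_hierarchy")
  validate_hierarchy(h)
  h
}

# Tree property: equal ancestor at scale s forces equal ancestor at s' > s.
validate_hierarchy <- function(h) {
  for (s in seq_len(h$n_scales)) {
    anc <- h$ancestor[[s]]
    present <- anc[!is.na(anc)]
    if (!setequal(unique(present), h$parcels[[s]]$id)) {
      stop("ancestor map at scale ", s,
           " is not surjective onto the parcel set", call. = FALSE)
    }
    if (s > 1) {
      prev <- h$ancestor[[s - 1]]
      keep <- !is.na(prev)
      cross <- unique(data.frame(child = prev[keep], parent = anc[keep]))
      if (anyDuplicated(cross$child)) {
        stop("ancestry violation: a scale-", s - 1,
             " parcel has two ancestors at scale ", s, call. = FALSE)
      }
    }
  }
  invisible(h)
}

#' Packaged five-scale gray-matter hierarchy
#'
#' The multi-granularity gray-matter parcellation used throughout the package:
#' 84 parcels at the finest scale (Scale-1), recombined hierarchically into
#' 58, 16, 6 and finally 4 parcels (left/right telencephalon and
#' diencephalon) at Scale-5.
#'
#' @return An `fcp_hierarchy` with node counts `c(84, 58, 16, 6, 4)`.
#' @export
fcp_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "gm_hierarchy_5scale.tsv",
                             package = "fcpyramid", mustWork = TRUE))
}

#' Number of parcels at a scale
#'
#' @param h An `fcp_hierarchy`.
#' @param scale Scale index (1 = finest).
#' @return Integer parcel count.
#' @export
node_count <- function(h, scale) {
  check_scale(h, scale)
  nrow(h$parcels[[scale]])
}

#' Parcel counts at every scale
#'
#' @param h An `fcp_hierarchy`.
#' @return Integer vector, finest scale first.
#' @export
node_counts <- function(h) {
  vapply(seq_len(h$n_scales), function(s) nrow(h$parcels[[s]]), integer(1))
}

check_scale <- function(h, scale) {
  if (length(scale) != 1 || is.na(scale) || scale < 1 || scale > h$n_scales ||
      scale != as.integer(scale)) {
    stop("scale must be a single integer in 1..", h$n_scales, call. = FALSE)
  }
  invisible(as.integer(scale))
}

#' Map finest-scale labels to a coarser scale
#'
#' Replaces every nonzero finest-scale label by the id of its ancestor parcel
#' at `target_scale`; zeros (background) are preserved. Works on vectors and
#' arrays (the shape is kept).
#'
#' @param h An `fcp_hierarchy`.
#' @param finest_labels Integer vector or array of finest-scale parcel ids,
#'   0 = background.
#' @param target_scale Scale to map to (1 returns the input unchanged).
#' @return Integer labels of the same shape at `target_scale`.
#' @export
coarsen_labels <- function(h, finest_labels, target_scale) {
  check_scale(h, target_scale)
  lab <- as.integer(finest_labels)
  nz <- lab != 0L
  bad <- nz & (lab < 1L | lab > length(h$ancestor[[1]]) |
                 is.na(h$ancestor[[1]][pmax(lab, 1L)]))
  if (any(bad)) {
    stop("unknown finest-scale label value(s): ",
         paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
  }
  out <- lab
  out[nz] <- h$ancestor[[target_scale]][lab[nz]]
  if (!is.null(dim(finest_labels))) dim(out) <- dim(finest_labels)
  out
}

#' @export
print.fcp_hierarchy <- function(x, ...) {
  cat("<fcp_hierarchy> ", x$n_scales, " scales; node counts: ",
      paste(node_counts(x), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Tidy a hierarchy into a long parcel table
#'
#' @param x An `fcp_hierarchy`.
#' @param ... Unused.
#' @return A tibble with one row per (scale, parcel): `scale`, `node_id`,
#'   `node_name`.
#' @method tidy fcp_hierarchy
#' @export
tidy.fcp_hierarchy <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_scales), function(s) {
    tibble::tibble(scale = s, node_id = x$parcels[[s]]$id,
                   node_name = x$parcels[[s]]$name)
  })
}

node_names <- function(h, scale) h$parcels[[scale]]$name

#' Look up parcel ids by name
#'
#' @param h An `fcp_hierarchy`.
#' @param names Character vector of parcel names.
#' @param scale Scale at which to resolve the names (default finest).
#' @return Integer parcel ids.
#' @export
parcel_id <- function(h, names, scale = 1) {
  check_scale(h, scale)
  idx <- match(names, h$parcels[[scale]]$name)
  if (anyNA(idx)) {
    stop("unknown parcel name(s) at scale ", scale, ": ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  h$parcels[[scale]]$id[idx]
}
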