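#' Bulk rED assignment table
#'
#' Encodes one of the three bulk-assignment strategies: `homogeneity` (whole
#' body water-equivalent, rED 1.0), `icru` (air 0.001 and bone 1.61 from ICRU
#' Report 46, every other ROI at its patient-specific mean), or `tailor`
#' (every ROI, including bone and air, at its patient-specific mean rED from
#' the planning CT). Overlaps are resolved by precedence: the
#' highest-precedence ROI containing a voxel wins.
#'
#' @param strategy `"homogeneity"`, `"icru"`, or `"tailor"`.
#' @param entries data frame with columns `roi`, `red`, `precedence` (higher
#'   rank wins; ranks must be unique).
#' @param background rED for voxels outside every ROI (default 0.001, air).
#' @export
assignment_table <- function(strategy, entries, background = 0.001) {
  strategy <- match.arg(strategy, c("homogeneity", "icru", "tailor"))
  entries <- as.data.frame(entries)
  stopifnot(all(c("roi", "red", "precedence") %in% names(entries)))
  if (any(entries$red < 0) || background < 0)
    stop("rED values must be >= 0", call. = FALSE)
  if (anyDuplicated(entries$precedence))
    stop("precedence ranks must be a total order", call. = FALSE)
  if (sum(entries$roi == "body") != 1L)
    stop("exactly one body entry is required", call. = FALSE)
  if (strategy == "homogeneity" &&
      entries$red[entries$roi == "body"] != 1.0)
    stop("homogeneity strategy requires the body entry at rED 1.0 exactly",
         call. = FALSE)
  if (strategy == "icru") {
    for (req in list(c("air", "0.001"), c("bone", "1.61"))) {
      i <- which(entries$roi == req[1])
      if (length(i) != 1L || entries$red[i] != as.numeric(req[2]))
        stop("icru strategy requires ", req[1], " = ", req[2], " exactly",
             call. = FALSE)
    }
  }
  structure(list(strategy = strategy,
                 entries = entries[order(entries$precedence), ],
                 background = background),
            class = "assignment_table")
}

# default overlap precedence, low to high: the bulk map is laid down body
# first, then targets, OARs, bone, and finally air, so that air cavities keep
# their (low) density even where they sit inside a PTV -- the behaviour that
# drives bulk-assignment accuracy at tissue--air interfaces.
default_role_precedence <- c(body = 0, target = 1, oar = 2, bone = 3, air = 4)

#' Build an assignment table from a per-ROI density summary
#'
#' @param strategy `"homogeneity"`, `"icru"`, or `"tailor"`.
#' @param summary an `roi_density_summary` (from [summarize_roi_red()]).
#' @param role_precedence named numeric vector of per-role base ranks, low to
#'   high; ties within a role are broken by summary order.
#' @param background rED outside the body.
#' @export
make_assignment_table <- function(strategy, summary,
                                  role_precedence = default_role_precedence,
                                  background = 0.001) {
  strategy <- match.arg(strategy, c("homogeneity", "icru", "tailor"))
  stopifnot(is.data.frame(summary))
  need <- if (strategy == "homogeneity") "body"
          else c("body", "bone", "air")
  for (nm in need)
    if (!nm %in% summary$roi ||
        (summary$n_voxels[summary$roi == nm] == 0))
      stop("config error: required ROI `", nm,
           "` is missing or empty in the density summary", call. = FALSE)
  if (strategy == "homogeneity") {
    entries <- data.frame(roi = "body", red = 1.0, precedence = 0)
    return(assignment_table(strategy, entries, background))
  }
  usable <- summary[!summary$empty, ]
  rank <- role_precedence[usable$role] * 1000 + seq_len(nrow(usable))
  red <- usable$mean_red
  if (strategy == "icru") {
    red[usable$roi == "air"] <- 0.001
    red[usable$roi == "bone"] <- 1.61
  }
  entries <- data.frame(roi = usable$roi, red = red, precedence = rank)
  assignment_table(strategy, entries, background)
}

#' Serialize / load an assignment table as YAML
#' @param table an `assignment_table`.
#' @param path YAML path.
#' @export
write_assignment_table <- function(table, path) {
  yaml::write_yaml(list(strategy = table$strategy,
                        background = table$background,
                        entries = lapply(seq_len(nrow(table$entries)),
                                         function(i) as.list(table$entries[i, ]))),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_assignment_table
#' @export
read_assignment_table <- function(path) {
  x <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(x$entries, as.data.frame))
  assignment_table(x$strategy, entries, x$background)
}

#' Build a synthetic CT (bulk rED map) from structures and a table
#'
#' Every voxel takes the rED of the highest-precedence ROI containing it;
#' voxels outside all ROIs take the background value. The result is
#' piecewise-constant over the ROI partition (the bulk property).
#'
#' @param structures a `structure_set` on the target grid (typically the
#'   pseudo-MRI grid after contour propagation).
#' @param table an `assignment_table` whose ROIs are all present.
#' @param summary optional `roi_density_summary` recorded as provenance.
#' @return object of class `synthetic_ct`: `red_map` (`image_volume`, rED),
#'   `strategy`, `table`, `summary`.
#' @export
build_sct <- function(structures, table, summary = NULL) {
  stopifnot(inherits(structures, "structure_set"),
            inherits(table, "assignment_table"))
  missing <- setdiff(table$entries$roi, names(structures$rois))
  if (length(missing) > 0)
    stop("config error: table ROI(s) missing from structures: ",
         paste(missing, collapse = ", "), call. = FALSE)
  g <- structures$geometry
  red <- array(table$background, dim = g$dims)
  # entries already ordered by ascending precedence: later writes win
  for (i in seq_len(nrow(table$entries))) {
    m <- structures$rois[[table$entries$roi[i]]]$mask
    red[m] <- table$entries$red[i]
  }
  structure(list(red_map = image_volume(red, spacing = g$spacing,
                                        origin = g$origin, unit = "rED"),
                 strategy = table$strategy, table = table, summary = summary),
            class = "synthetic_ct")
}

#' @export
print.synthetic_ct <- function(x, ...) {
  cat(sprintf("<synthetic_ct> strategy %s, %d assignment entries\n",
              x$strategy, nrow(x$table$entries)))
  invisible(x)
}
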