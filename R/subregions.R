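#' Femorotibial subregion vocabulary
#'
#' The 16 femorotibial subregions used throughout the package: five subregions
#' (central, external, internal, anterior, posterior) on each tibial plateau
#' (MT = medial tibia, LT = lateral tibia) and three (central, external,
#' internal) on each weight-bearing femoral condyle (cMF = central medial
#' femur, cLF = central lateral femur). Mean cartilage thickness (ThCtAB) is
#' carried per subregion in micrometres.
#'
#' @return Character vector of the 16 canonical subregion labels.
#' @export
#' @examples
#' subregion_labels()
subregion_labels <- function() {
  c(
    paste0(c("c", "e", "i", "a", "p"), "MT"),
    paste0(c("c", "e", "i", "a", "p"), "LT"),
    paste0(c("c", "e", "i"), "cMF"),
    paste0(c("c", "e", "i"), "cLF")
  )
}

# column names used for thickness fields in the visits table
thickness_columns <- function() paste0("th_", subregion_labels())

#' Region specification
#'
#' A region is a tibial plate (a set of tibial subregions averaged with
#' weights), a femoral plate, or a femorotibial aggregate in which the tibial
#' and femoral plate values are summed. This reproduces the usual compartment
#' variables: e.g. the central medial femorotibial compartment (cMFTC) is the
#' sum of the central medial tibial subregion (cMT) and the central
#' weight-bearing medial femoral subregion (ccMF), while the total medial
#' compartment (MFTC) sums the medial tibial plate mean and the central
#' medial femoral plate mean.
#'
#' @param name Region name.
#' @param tibial Character vector of tibial member subregions (may be empty).
#' @param femoral Character vector of femoral member subregions (may be empty).
#' @param tibial_weights,femoral_weights Optional positive weights used when
#'   averaging subregions within a plate; equal weights by default (subregion
#'   areas are not part of the data model).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, tibial = character(), femoral = character(),
                        tibial_weights = NULL, femoral_weights = NULL) {
  all_labels <- subregion_labels()
  members <- c(tibial, femoral)
  if (length(members) == 0L) stop("region must have at least one member subregion")
  unknown <- setdiff(members, all_labels)
  if (length(unknown) > 0L) {
    stop("unknown subregion label(s): ", paste(unknown, collapse = ", "))
  }
  norm_w <- function(w, m, what) {
    if (length(m) == 0L) return(numeric())
    if (is.null(w)) w <- rep(1, length(m))
    if (length(w) != length(m) || any(w <= 0)) {
      stop("invalid ", what, " weights")
    }
    w / sum(w)
  }
  structure(
    list(
      name = name,
      tibial = tibial,
      femoral = femoral,
      tibial_weights = norm_w(tibial_weights, tibial, "tibial"),
      femoral_weights = norm_w(femoral_weights, femoral, "femoral")
    ),
    class = "region_spec"
  )
}

#' Standard femorotibial regions
#'
#' Named list of the standard region specifications: single central
#' subregions (cMT, ccMF, cLT, ccLF), plate means (MT, LT, cMF, cLF), central
#' compartment aggregates (cMFTC = cMT + ccMF, cLFTC = cLT + ccLF) and total
#' compartment aggregates (MFTC = MT plate + cMF plate, LFTC likewise).
#'
#' @return Named list of `region_spec` objects.
#' @export
#' @examples
#' names(ftc_regions())
ftc_regions <- function() {
  mt <- paste0(c("c", "e", "i", "a", "p"), "MT")
  lt <- paste0(c("c", "e", "i", "a", "p"), "LT")
  cmf <- paste0(c("c", "e", "i"), "cMF")
  clf <- paste0(c("c", "e", "i"), "cLF")
  list(
    cMT   = region_spec("cMT", tibial = "cMT"),
    ccMF  = region_spec("ccMF", femoral = "ccMF"),
    cLT   = region_spec("cLT", tibial = "cLT"),
    ccLF  = region_spec("ccLF", femoral = "ccLF"),
    MT    = region_spec("MT", tibial = mt),
    LT    = region_spec("LT", tibial = lt),
    cMF   = region_spec("cMF", femoral = cmf),
    cLF   = region_spec("cLF", femoral = clf),
    cMFTC = region_spec("cMFTC", tibial = "cMT", femoral = "ccMF"),
    cLFTC = region_spec("cLFTC", tibial = "cLT", femoral = "ccLF"),
    MFTC  = region_spec("MFTC", tibial = mt, femoral = cmf),
    LFTC  = region_spec("LFTC", tibial = lt, femoral = clf)
  )
}

resolve_region <- function(region) {
  if (inherits(region, "region_spec")) return(region)
  if (is.character(region) && length(region) == 1L) {
    regs <- ftc_regions()
    if (!region %in% names(regs)) {
      stop("unknown region name: ", region)
    }
    return(regs[[region]])
  }
  stop("region must be a region_spec or a standard region name")
}
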