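# Class-scheme grouping maps between SS classification conventions.

#' Construct a class map between two SS schemes
#'
#' A surjective assignment of every source class to a target class, used to
#' compare compositions produced under different classification
#' conventions.  An optional completion rule fills one target class as the
#' complement of the others (estimators that only report structured
#' fractions).
#'
#' @param source_scheme,target_scheme Scheme names.
#' @param assignment Named character vector: `names()` are source classes,
#'   values are target classes.  Every source class appears exactly once.
#' @param completion_class Optional name of a target class set to
#'   `1 - sum(other target fractions)` after grouping.
#' @return Object of class `class_map`.
#' @export
class_map <- function(source_scheme, target_scheme, assignment,
                      completion_class = NULL) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("assignment must map every source class exactly once", call. = FALSE)
  targets <- unique(unname(assignment))
  if (!is.null(completion_class)) {
    if (!completion_class %in% targets)
      targets <- c(targets, completion_class)
  }
  structure(list(source_scheme = source_scheme,
                 target_scheme = target_scheme,
                 assignment = assignment,
                 target_classes = targets,
                 completion_class = completion_class),
            class = "class_map")
}

#' Group SS fractions into another class scheme
#'
#' Each target fraction is the sum of its assigned source fractions, so the
#' total fraction mass is conserved exactly (before any completion rule).
#' The completion rule, if present, is applied last.
#'
#' @param F An [ss_composition] in the map's source scheme.
#' @param map A [class_map].
#' @return An [ss_composition] in the target scheme.
#' @export
group_classes <- function(F, map) {
  stopifnot(inherits(F, "ss_composition"), inherits(map, "class_map"))
  if (!identical(F$scheme, map$source_scheme))
    stop("composition scheme does not match map source scheme", call. = FALSE)
  src <- names(F$fractions)
  unmapped <- setdiff(src, names(map$assignment))
  if (length(unmapped))
    stop("unmapped class: ", paste(unmapped, collapse = ", "), call. = FALSE)
  out <- stats::setNames(numeric(length(map$target_classes)),
                         map$target_classes)
  for (cls in src)
    out[map$assignment[[cls]]] <- out[map$assignment[[cls]]] + F$fractions[[cls]]
  if (abs(sum(out[unique(unname(map$assignment))]) - sum(F$fractions)) > 1e-9)
    stop("grouping failed to conserve fraction mass", call. = FALSE)
  if (!is.null(map$completion_class)) {
    others <- setdiff(map$target_classes, map$completion_class)
    out[map$completion_class] <- 1 - sum(out[others])
  }
  ss_composition(out, scheme = map$target_scheme, pure = F$pure)
}

#' Shipped class maps
#'
#' Grouping tables for the classification schemes used in CD-based SS
#' assessment.  The grouping *logic* between BESTSEL and HBSS is fixed
#' (Helix-1/Helix-2 merge into Helix; the three anti-parallel strand
#' classes map to the left-handed, non-twisted and right-handed HBSS
#' strands; all parallel strands merge; everything else merges into
#' Other), and the K2D3 coil completion is
#' `F_Coil = 1 - (F_Beta + F_Alpha)`.  The member lists of the
#' DISICL/DSSP/HBSS reductions are editable configuration: pass your own
#' `assignment` to [class_map()] to override them.
#'
#' @param name One of `"bestsel6"` (BESTSEL 8-class to 6), `"hbss6"`
#'   (HBSS to the matching 6), `"k2d3"` (3-class with coil completion),
#'   `"disicl3"`, `"disicl6"`, `"dssp4"`, `"hbss5"`.
#' @return A [class_map].
#' @export
shipped_class_map <- function(name = c("bestsel6", "hbss6", "k2d3",
                                       "disicl3", "disicl6", "dssp4",
                                       "hbss5")) {
  name <- match.arg(name)
  switch(name,
    bestsel6 = class_map("BESTSEL8", "SS6", c(
      Helix1 = "Helix", Helix2 = "Helix",
      Anti1 = "Anti1", Anti2 = "Anti2", Anti3 = "Anti3",
      Parallel = "Parallel", Turn = "Other", Others = "Other")),
    hbss6 = class_map("HBSS", "SS6", c(
      Helix4 = "Helix",
      AntiL = "Anti1", AntiN = "Anti2", AntiR = "Anti3",
      Para1 = "Parallel", Para2 = "Parallel",
      Helix3 = "Other", Helix5 = "Other", Turn = "Other", Coil = "Other")),
    k2d3 = class_map("DISICL3", "K2D3", c(
      Alpha = "Alpha", Beta = "Beta", Coil = "Coil"),
      completion_class = "Coil"),
    disicl3 = class_map("DISICL", "DISICL3", c(
      ALH = "Alpha", HEL3 = "Alpha", PIH = "Alpha",
      EXB = "Beta", NTB = "Beta", BRI = "Beta",
      TUR = "Coil", SLP = "Coil", UNC = "Coil")),
    disicl6 = class_map("DISICL", "DISICL6", c(
      ALH = "Alpha", HEL3 = "Helix3", PIH = "Alpha",
      EXB = "Strand", NTB = "Strand", BRI = "Bridge",
      TUR = "Turn", SLP = "Turn", UNC = "Coil")),
    dssp4 = class_map("DSSP", "DSSP4", c(
      H = "Helix", G = "Helix", I = "Helix",
      E = "Sheet", B = "Sheet",
      T = "Turn", S = "Turn", C = "Coil")),
    hbss5 = class_map("HBSS", "HBSS5", c(
      Helix4 = "Helix", Helix3 = "Helix", Helix5 = "Helix",
      AntiL = "Anti", AntiN = "Anti", AntiR = "Anti",
      Para1 = "Para", Para2 = "Para",
      Turn = "Turn", Coil = "Coil")))
}
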