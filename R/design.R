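#' Cross designs for reciprocal hybrid series
#'
#' A `cross_design` records how samples map to cross groups, which parental
#' genotype was the maternal and which the paternal parent of each group, and
#' the parental ploidies. Everything downstream that needs to translate a
#' genotype allele (e.g. "L4") into a parent-of-origin (maternal/paternal)
#' does so through this object: the same genotype allele is maternal in one
#' reciprocal cross and paternal in the other, and that resolution is the crux
#' of any parent-of-origin analysis.
#'
#' Group classes are derived, never stored by the user:
#' * `parental_self` — maternal and paternal genotypes identical;
#' * `2x_hybrid` — two distinct diploid parents;
#' * `3x_maternal_excess` — tetraploid mother, diploid father;
#' * `3x_paternal_excess` — diploid mother, tetraploid father;
#' * `4x_hybrid` — two distinct tetraploid parents.
#'
#' @param groups data.frame with columns `group`, `maternal_parent`,
#'   `paternal_parent`, one row per cross group.
#' @param samples data.frame with columns `sample`, `group`.
#' @param ploidy named integer vector, parental genotype -> ploidy (2 or 4).
#' @return An object of class `cross_design` with elements `groups` (with the
#'   derived `group_class` column and parental ploidies), `samples`, `ploidy`.
#' @examples
#' d <- cross_design(
#'   groups  = data.frame(group = "L2xL4", maternal_parent = "L2",
#'                        paternal_parent = "L4"),
#'   samples = data.frame(sample = c("a", "b", "c"), group = "L2xL4"),
#'   ploidy  = c(L2 = 2, L4 = 4)
#' )
#' d$groups$group_class  # "3x_paternal_excess"
#' @export
cross_design <- function(groups, samples, ploidy) {
  stopifnot(is.data.frame(groups), is.data.frame(samples))
  need <- c("group", "maternal_parent", "paternal_parent")
  if (!all(need %in% names(groups)))
    stop("`groups` must have columns: ", paste(need, collapse = ", "))
  if (!all(c("sample", "group") %in% names(samples)))
    stop("`samples` must have columns: sample, group")
  if (nrow(samples) == 0L)
    stop("design has an empty sample list")
  if (anyDuplicated(groups$group))
    stop("duplicated group label: ",
         groups$group[duplicated(groups$group)][1L])
  dup <- samples$sample[duplicated(samples$sample)]
  if (length(dup))
    stop("sample assigned to more than one group: ", dup[1L])
  if (!all(samples$group %in% groups$group))
    stop("sample group not declared: ",
         setdiff(samples$group, groups$group)[1L])

  parents <- unique(c(groups$maternal_parent, groups$paternal_parent))
  missing_p <- setdiff(parents, names(ploidy))
  if (length(missing_p))
    stop("no ploidy given for parent genotype: ", missing_p[1L])
  bad <- names(ploidy)[!ploidy %in% c(2L, 4L)]
  if (length(bad))
    stop("unknown ploidy for parent ", bad[1L], ": ploidies must be 2 or 4")

  groups$maternal_ploidy <- as.integer(ploidy[groups$maternal_parent])
  groups$paternal_ploidy <- as.integer(ploidy[groups$paternal_parent])
  groups$group_class <- derive_group_class(groups)

  empty <- setdiff(groups$group, samples$group)
  if (length(empty))
    stop("group has no samples (replicate count must be >= 1): ", empty[1L])

  structure(
    list(groups = groups,
         samples = samples[, c("sample", "group")],
         ploidy = ploidy),
    class = "cross_design"
  )
}

derive_group_class <- function(groups) {
  mapply(function(m, p, pm, pp) {
    if (m == p) return("parental_self")
    tot <- pm + pp
    if (tot == 4L) return("2x_hybrid")
    if (tot == 8L) return("4x_hybrid")
    if (pm == 4L) "3x_maternal_excess" else "3x_paternal_excess"
  }, groups$maternal_parent, groups$paternal_parent,
     groups$maternal_ploidy, groups$paternal_ploidy,
     USE.NAMES = FALSE)
}

#' @export
print.cross_design <- function(x, ...) {
  cat("cross_design:", nrow(x$groups), "groups,",
      nrow(x$samples), "samples\n")
  tab <- table(x$samples$group)[x$groups$group]
  df <- x$groups
  df$n_samples <- as.integer(tab)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a cross design from a YAML file
#'
#' Expected layout:
#' ```yaml
#' parents: {L2: 2, L4: 4}
#' groups:
#'   L2xL4: {maternal: L2, paternal: L4, samples: [s1, s2, s3]}
#' ```
#' An optional `class:` entry per group is validated against the class derived
#' from the parental ploidies and rejected on mismatch.
#'
#' @param path path to the YAML design file.
#' @return A validated [cross_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$parents) || is.null(y$groups))
    stop("design YAML must have `parents` and `groups` blocks")
  ploidy <- unlist(y$parents)
  groups <- data.frame(
    group = names(y$groups),
    maternal_parent = vapply(y$groups, function(g) g$maternal, ""),
    paternal_parent = vapply(y$groups, function(g) g$paternal, ""),
    row.names = NULL
  )
  samples <- do.call(rbind, lapply(names(y$groups), function(gn) {
    s <- unlist(y$groups[[gn]]$samples)
    if (is.null(s)) s <- character(0)
    if (length(s) == 0L)
      data.frame(sample = character(0), group = character(0))
    else data.frame(sample = s, group = gn)
  }))
  d <- cross_design(groups, samples, ploidy)
  declared <- vapply(y$groups, function(g)
    if (is.null(g$class)) NA_character_ else g$class, "")
  mism <- which(!is.na(declared) & declared != d$groups$group_class)
  if (length(mism))
    stop("declared class '", declared[mism[1L]], "' for group ",
         d$groups$group[mism[1L]], " conflicts with derived class '",
         d$groups$group_class[mism[1L]], "'")
  d
}

#' Write a cross design to YAML
#' @param design a [cross_design()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  y <- list(
    parents = as.list(stats::setNames(as.integer(design$ploidy),
                                      names(design$ploidy))),
    groups = stats::setNames(lapply(seq_len(nrow(design$groups)), function(i) {
      g <- design$groups[i, ]
      list(maternal = g$maternal_parent, paternal = g$paternal_parent,
           samples = as.list(replicates_of(design, g$group)))
    }), design$groups$group)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Samples belonging to one group
#' @param design a [cross_design()].
#' @param group group label.
#' @return character vector of sample IDs.
#' @export
replicates_of <- function(design, group) {
  if (!group %in% design$groups$group) stop("unknown group: ", group)
  design$samples$sample[design$samples$group == group]
}

#' Groups of a given class
#' @param design a [cross_design()].
#' @param class one or more group-class labels.
#' @return character vector of group labels.
#' @export
groups_of_class <- function(design, class) {
  design$groups$group[design$groups$group_class %in% class]
}

group_row <- function(design, group) {
  i <- match(group, design$groups$group)
  if (is.na(i)) stop("unknown group: ", group)
  design$groups[i, ]
}

#' Parent-of-origin dosage null for a cross
#'
#' In a triploid the tetraploid parent contributes two of the three genome
#' copies, so absent regulation its allele is expected to carry 2/3 of the
#' allelic reads (a 2:1 ratio); balanced crosses expect 1/2 each. The expected
#' fraction of an allele is its parent's contributed genome copies over the
#' total: ploidy_parent / (ploidy_maternal + ploidy_paternal).
#'
#' @param design a [cross_design()].
#' @param group group (cross) label.
#' @return list with `group`, `maternal_parent`, `paternal_parent`,
#'   `f_maternal`, `f_paternal` (expected read fractions, summing to 1).
#' @examples
#' # 4x mother x 2x father: maternal allele expected at 2/3
#' @export
dosage_null <- function(design, group) {
  g <- group_row(design, group)
  tot <- g$maternal_ploidy + g$paternal_ploidy
  list(group = group,
       maternal_parent = g$maternal_parent,
       paternal_parent = g$paternal_parent,
       f_maternal = g$maternal_ploidy / tot,
       f_paternal = g$paternal_ploidy / tot)
}

#' The default synthetic study design
#'
#' Emulates a reciprocal hybrid series over two diploid (L2, R2) and two
#' tetraploid (L4, R4) parental genotypes: parental selfs, reciprocal diploid
#' hybrids, reciprocal triploids (maternal- and paternal-excess), and
#' reciprocal tetraploid hybrids, with `n_reps` biological replicates per
#' group (the study design uses 3).
#'
#' @param n_reps replicates per group.
#' @return A [cross_design()].
#' @export
default_design <- function(n_reps = 3L) {
  groups <- data.frame(
    group = c("L2self", "L4self", "R2self", "R4self",
              "L2xL4", "L4xL2", "R2xL2", "L2xR2", "L4xR4", "R4xL4"),
    maternal_parent = c("L2", "L4", "R2", "R4",
                        "L2", "L4", "R2", "L2", "L4", "R4"),
    paternal_parent = c("L2", "L4", "R2", "R4",
                        "L4", "L2", "L2", "R2", "R4", "L4")
  )
  samples <- do.call(rbind, lapply(groups$group, function(g)
    data.frame(sample = paste0(g, "_r", seq_len(n_reps)), group = g)))
  cross_design(groups, samples,
               ploidy = c(L2 = 2L, L4 = 4L, R2 = 2L, R4 = 4L))
}
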