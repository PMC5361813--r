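#' Construct a pedigree table
#'
#' A pedigree is a plain `data.frame` with one row per sample and columns
#' `sample_id`, `family_id`, `father_id`, `mother_id` (both `NA` when the
#' parent is not in the study), `sex` (`"male"`, `"female"`, `"unknown"`) and
#' `affected` (`"affected"`, `"unaffected"`, `"unknown"`).
#'
#' @param sample_id,family_id character vectors of equal length.
#' @param father_id,mother_id character vectors; use `NA` for absent parents.
#' @param sex character vector in `male/female/unknown`.
#' @param affected character vector in `affected/unaffected/unknown`.
#' @return a `data.frame` of class `pedigree`.
#' @export
pedigree <- function(sample_id, family_id, father_id = NA_character_,
                     mother_id = NA_character_, sex = "unknown",
                     affected = "unknown") {
  ped <- data.frame(sample_id = as.character(sample_id),
                    family_id = as.character(family_id),
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    sex = as.character(sex),
                    affected = as.character(affected),
                    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

#' @noRd
validate_pedigree <- function(ped) {
  dup <- ped$sample_id[duplicated(ped$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in pedigree: ", paste(unique(dup), collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    refs <- ped[[col]]
    bad <- !is.na(refs) & !(refs %in% ped$sample_id)
    if (any(bad))
      stop("unresolvable ", col, " in pedigree: ",
           paste(unique(refs[bad]), collapse = ", "))
  }
  stopifnot(all(ped$sex %in% c("male", "female", "unknown")),
            all(ped$affected %in% c("affected", "unaffected", "unknown")))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a 6-column PED file
#'
#' Whitespace-delimited PED: family, sample, father, mother, sex (1 = male,
#' 2 = female, other = unknown), phenotype (1 = unaffected, 2 = affected,
#' other = unknown). Parent code `"0"` maps to `NA` (parent not sampled).
#'
#' @param path path to a PED file.
#' @return a [pedigree()] data frame, rows in file order.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("PED file must have 6 columns: ", path)
  sex <- c("1" = "male", "2" = "female")[tab[[5]]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[tab[[6]]]
  aff[is.na(aff)] <- "unknown"
  pedigree(sample_id = tab[[2]], family_id = tab[[1]],
           father_id = ifelse(tab[[3]] == "0", NA_character_, tab[[3]]),
           mother_id = ifelse(tab[[4]] == "0", NA_character_, tab[[4]]),
           sex = unname(sex), affected = unname(aff))
}

#' Write a pedigree to a 6-column PED file
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(unaffected = "1", affected = "2", unknown = "0")[ped$affected]
  out <- data.frame(ped$family_id, ped$sample_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    unname(sex), unname(aff))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# children with both parents present in the pedigree (trio-analyzable)
#' @noRd
trio_children <- function(ped, family_id = NULL, affected_only = TRUE) {
  rows <- !is.na(ped$father_id) & !is.na(ped$mother_id)
  if (!is.null(family_id)) rows <- rows & ped$family_id == family_id
  if (affected_only) rows <- rows & ped$affected == "affected"
  ped$sample_id[rows]
}

#' @noRd
parents_of <- function(ped, sample_id) {
  i <- match(sample_id, ped$sample_id)
  if (is.na(i)) stop("sample not in pedigree: ", sample_id)
  list(father = ped$father_id[i], mother = ped$mother_id[i])
}
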