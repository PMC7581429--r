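#' Read a 6-column PED pedigree file
#'
#' Columns are family id, individual id, father id, mother id, sex
#' (1 = male, 2 = female, other = unknown) and phenotype (2 = affected,
#' 1 = unaffected, other = unknown). `0` in the parent columns means the
#' parent is absent.
#'
#' The proband defaults to the unique affected member with both parents
#' present in the pedigree; zero or multiple affected offspring require an
#' explicit `proband_id`. Unaffected full siblings of the proband are
#' identified as members sharing both parents and coded unaffected.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @param proband_id Optional explicit proband override.
#' @return An object of class `pedigree`: a list with `members` (tibble with
#'   `sample_id`, `father_id`, `mother_id`, `sex`, `affected`), `proband_id`,
#'   `father_id`, `mother_id` and `sibling_ids` (unaffected full siblings).
#' @export
read_pedigree <- function(path, proband_id = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother", "sex", "phenotype"))
  members <- tibble::tibble(
    sample_id = as.character(raw$id),
    father_id = ifelse(raw$father %in% c("0", 0), NA_character_, as.character(raw$father)),
    mother_id = ifelse(raw$mother %in% c("0", 0), NA_character_, as.character(raw$mother)),
    sex = dplyr::case_when(raw$sex == 1 ~ "male", raw$sex == 2 ~ "female", TRUE ~ "unknown"),
    affected = dplyr::case_when(raw$phenotype == 2 ~ "affected",
                                raw$phenotype == 1 ~ "unaffected",
                                TRUE ~ "unknown")
  )
  new_pedigree(members, proband_id = proband_id)
}

#' Construct a pedigree from a members table
#'
#' @param members Tibble with columns `sample_id`, `father_id`, `mother_id`,
#'   `sex`, `affected` (see [read_pedigree()]).
#' @param proband_id Optional explicit proband; defaults to the unique
#'   affected member with both parents present.
#' @return A `pedigree` object.
#' @export
new_pedigree <- function(members, proband_id = NULL) {
  if (anyDuplicated(members$sample_id)) stop("Duplicate sample ids in pedigree", call. = FALSE)
  known <- members$sample_id
  bad_parent <- stats::na.omit(setdiff(c(members$father_id, members$mother_id), known))
  if (length(bad_parent) > 0) {
    stop("Parent id(s) not present in pedigree: ", paste(bad_parent, collapse = ", "), call. = FALSE)
  }
  check_no_ancestry_cycle(members)
  has_parents <- !is.na(members$father_id) & !is.na(members$mother_id)
  if (is.null(proband_id)) {
    cand <- members$sample_id[members$affected == "affected" & has_parents]
    if (length(cand) == 0) {
      stop("No affected offspring with both parents present; supply proband_id", call. = FALSE)
    }
    if (length(cand) > 1) {
      stop("Multiple affected offspring (", paste(cand, collapse = ", "),
           "); supply proband_id", call. = FALSE)
    }
    proband_id <- cand
  } else if (!proband_id %in% known) {
    stop("proband_id ", proband_id, " not in pedigree", call. = FALSE)
  }
  pb <- members[members$sample_id == proband_id, ]
  if (is.na(pb$father_id) || is.na(pb$mother_id)) {
    stop("Proband must have both parents present in the pedigree", call. = FALSE)
  }
  sibs <- members$sample_id[
    members$sample_id != proband_id &
      !is.na(members$father_id) & members$father_id == pb$father_id &
      !is.na(members$mother_id) & members$mother_id == pb$mother_id &
      members$affected == "unaffected"
  ]
  structure(
    list(members = members, proband_id = proband_id,
         father_id = pb$father_id, mother_id = pb$mother_id,
         sibling_ids = sibs),
    class = "pedigree"
  )
}

check_no_ancestry_cycle <- function(members) {
  idx <- stats::setNames(seq_len(nrow(members)), members$sample_id)
  for (start in members$sample_id) {
    seen <- character(0)
    frontier <- start
    while (length(frontier) > 0) {
      cur <- frontier[1]; frontier <- frontier[-1]
      row <- members[idx[[cur]], ]
      for (p in c(row$father_id, row$mother_id)) {
        if (is.na(p)) next
        if (p == start) stop("Pedigree cycle: ", start, " is its own ancestor", call. = FALSE)
        if (!p %in% seen) { seen <- c(seen, p); frontier <- c(frontier, p) }
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x$members), "members; proband", x$proband_id,
      "(father", x$father_id, ", mother", x$mother_id, ");",
      length(x$sibling_ids), "unaffected sibling(s)\n")
  invisible(x)
}

proband_sex <- function(pedigree) {
  pedigree$members$sex[pedigree$members$sample_id == pedigree$proband_id]
}
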