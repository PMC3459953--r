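#' Construct and validate a pedigree
#'
#' Builds a validated pedigree from a member table. Validation enforces
#' the structural invariants the likelihood machinery relies on: unique
#' individual ids, parent ids that resolve within the family, parents
#' recorded both-or-neither (an individual with a single recorded parent
#' is rejected so that every non-founder has two parents), an acyclic
#' parent graph (nobody is their own ancestor), at least one founder,
#' and at most one index case.
#'
#' @param members A data frame with columns \code{individual_id},
#'   \code{family_id}, \code{father_id}, \code{mother_id} (\code{NA} for
#'   founders), \code{sex} (\code{"male"}, \code{"female"},
#'   \code{"unknown"}), \code{affection} (\code{"affected"},
#'   \code{"unaffected"}, \code{"unknown"}); optional columns
#'   \code{cancer_type}, \code{age_dx_or_censor}, \code{is_sequenced},
#'   \code{is_index}.
#' @return An object of class \code{pedigree}: a list with
#'   \code{family_id} and a \code{members} tibble (founders first is not
#'   guaranteed; use [founders()]).
#' @export
new_pedigree <- function(members) {
  stopifnot(is.data.frame(members))
  req <- c("individual_id", "family_id", "father_id", "mother_id",
           "sex", "affection")
  miss <- setdiff(req, names(members))
  if (length(miss)) {
    stop("pedigree members lack required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  members <- as_tibble(members)
  if (!"cancer_type" %in% names(members)) members$cancer_type <- NA_character_
  if (!"age_dx_or_censor" %in% names(members)) members$age_dx_or_censor <- NA_real_
  if (!"is_sequenced" %in% names(members)) members$is_sequenced <- FALSE
  if (!"is_index" %in% names(members)) members$is_index <- FALSE
  members$individual_id <- as.character(members$individual_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)

  fam <- unique(members$family_id)
  if (length(fam) != 1L) {
    stop("a pedigree must contain exactly one family_id, got: ",
         paste(fam, collapse = ", "), call. = FALSE)
  }
  dup <- members$individual_id[duplicated(members$individual_id)]
  if (length(dup)) {
    stop("duplicate individual id(s) in family ", fam, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  one_parent <- xor(is.na(members$father_id), is.na(members$mother_id))
  if (any(one_parent)) {
    stop("individual(s) with exactly one recorded parent in family ", fam,
         ": ", paste(members$individual_id[one_parent], collapse = ", "),
         "; record both parents or neither", call. = FALSE)
  }
  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(members[[col]]) & !members[[col]] %in% members$individual_id
    if (any(bad)) {
      stop("unresolvable ", sub("_id", "", col), " id(s) in family ", fam,
           ": ", paste(members[[col]][bad], collapse = ", "), call. = FALSE)
    }
  }
  self_parent <- !is.na(members$father_id) &
    (members$father_id == members$individual_id |
       members$mother_id == members$individual_id)
  if (any(self_parent)) {
    stop("pedigree cycle in family ", fam, ": individual ",
         members$individual_id[which(self_parent)[1]],
         " is listed as its own parent", call. = FALSE)
  }
  # ancestor cycles via the directed parent -> child graph
  kids <- members[!is.na(members$father_id), ]
  if (nrow(kids)) {
    edges <- rbind(cbind(kids$father_id, kids$individual_id),
                   cbind(kids$mother_id, kids$individual_id))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      in_cycle <- names(comp$membership)[comp$membership %in%
                                           which(comp$csize > 1L)]
      who <- if (length(in_cycle)) in_cycle[1] else kids$individual_id[1]
      stop("pedigree cycle in family ", fam, " involving individual ",
           who, call. = FALSE)
    }
  }
  n_founders <- sum(is.na(members$father_id))
  if (n_founders < 1L) {
    stop("family ", fam, " has no founder", call. = FALSE)
  }
  if (sum(members$is_index, na.rm = TRUE) > 1L) {
    stop("family ", fam, " has more than one index case", call. = FALSE)
  }
  canon <- c("individual_id", "family_id", "father_id", "mother_id", "sex",
             "affection", "cancer_type", "age_dx_or_censor", "is_sequenced",
             "is_index")
  members <- members[, c(canon, setdiff(names(members), canon))]
  structure(list(family_id = as.character(fam), members = members),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  m <- x$members
  cat("<pedigree> family ", x$family_id, ": ", nrow(m), " members, ",
      sum(is.na(m$father_id)), " founders, ",
      sum(m$affection == "affected", na.rm = TRUE), " affected, ",
      sum(m$is_sequenced, na.rm = TRUE), " sequenced\n", sep = "")
  invisible(x)
}

#' Founders of a pedigree
#'
#' @param pedigree A \code{pedigree} object.
#' @return Tibble of members with no recorded parents.
#' @export
founders <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  pedigree$members[is.na(pedigree$members$father_id), ]
}

#' Detect mating loops in a pedigree
#'
#' Builds the marriage graph (one node per individual plus one node per
#' parental union, with edges union-father, union-mother, union-child)
#' and reports whether it contains a cycle. Inbreeding and marriage
#' loops make this graph cyclic; the peeling likelihood refuses such
#' pedigrees.
#'
#' @param pedigree A \code{pedigree} object.
#' @return Logical scalar.
#' @export
has_mating_loop <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  kids <- pedigree$members[!is.na(pedigree$members$father_id), ]
  if (!nrow(kids)) return(FALSE)
  union_id <- paste0("u:", kids$father_id, "|", kids$mother_id)
  edges <- rbind(
    unique(cbind(union_id, kids$father_id)),
    unique(cbind(union_id, kids$mother_id)),
    cbind(union_id, kids$individual_id)
  )
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  # a forest has |E| = |V| - #components
  igraph::ecount(g) > igraph::vcount(g) - igraph::count_components(g)
}

#' Read pedigrees from a PED file with an optional phenotype sidecar
#'
#' Reads a 6-column whitespace-delimited pre-makeped PED file
#' (family, individual, father, mother, sex, affection; unknown parents
#' coded \code{"0"}) and, when given, a tab-separated phenotype sidecar
#' keyed by (\code{family_id}, \code{individual_id}) carrying
#' \code{affection}, \code{cancer_type}, \code{age} and optionally
#' \code{is_sequenced}/\code{is_index} flags that 6-column PED cannot
#' hold. Sidecar affection, when present, overrides the PED code.
#'
#' @param ped_path Path to the PED file.
#' @param phenotype_path Optional path to the phenotype TSV.
#' @return Named list of validated \code{pedigree} objects, one per
#'   family.
#' @export
read_pedigree <- function(ped_path, phenotype_path = NULL) {
  if (!file.exists(ped_path)) {
    stop("PED file not found: ", ped_path, call. = FALSE)
  }
  ped <- read.table(ped_path, header = FALSE, colClasses = "character",
                    comment.char = "#")
  if (ncol(ped) < 6L) {
    stop("PED file must have 6 columns, found ", ncol(ped), call. = FALSE)
  }
  names(ped)[1:6] <- c("family_id", "individual_id", "father_id",
                       "mother_id", "sex_code", "aff_code")
  members <- tibble(
    family_id = ped$family_id,
    individual_id = ped$individual_id,
    father_id = ifelse(ped$father_id == "0", NA_character_, ped$father_id),
    mother_id = ifelse(ped$mother_id == "0", NA_character_, ped$mother_id),
    sex = unname(c("1" = "male", "2" = "female")[ped$sex_code]),
    affection = unname(c("1" = "unaffected", "2" = "affected")[ped$aff_code])
  )
  members$sex[is.na(members$sex)] <- "unknown"
  members$affection[is.na(members$affection)] <- "unknown"

  if (!is.null(phenotype_path)) {
    if (!file.exists(phenotype_path)) {
      stop("phenotype file not found: ", phenotype_path, call. = FALSE)
    }
    phen <- read.table(phenotype_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#",
                       colClasses = "character")
    req <- c("family_id", "individual_id")
    if (!all(req %in% names(phen))) {
      stop("phenotype sidecar must contain family_id and individual_id",
           call. = FALSE)
    }
    key <- paste(members$family_id, members$individual_id)
    pkey <- paste(phen$family_id, phen$individual_id)
    idx <- match(key, pkey)
    grab <- function(col) if (col %in% names(phen)) phen[[col]][idx] else NULL
    aff <- grab("affection")
    if (!is.null(aff)) {
      members$affection <- ifelse(is.na(aff), members$affection, aff)
    }
    ct <- grab("cancer_type")
    if (!is.null(ct)) members$cancer_type <- ifelse(ct == "", NA_character_, ct)
    age <- grab("age")
    if (!is.null(age)) members$age_dx_or_censor <- suppressWarnings(as.numeric(age))
    for (flag in c("is_sequenced", "is_index")) {
      v <- grab(flag)
      if (!is.null(v)) members[[flag]] <- !is.na(v) & v %in% c("TRUE", "true", "1")
    }
  }
  fams <- split(members, members$family_id)
  peds <- lapply(fams, new_pedigree)
  peds[order(names(peds))]
}

#' Write pedigrees to PED and phenotype sidecar files
#'
#' Inverse of [read_pedigree()]: emits a 6-column PED file and a
#' tab-separated phenotype sidecar (affection, cancer type, age,
#' sequenced/index flags) for a list of pedigrees.
#'
#' @param pedigrees Named list of \code{pedigree} objects.
#' @param ped_path,phenotype_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_pedigree <- function(pedigrees, ped_path, phenotype_path) {
  members <- dplyr::bind_rows(lapply(pedigrees, function(p) p$members))
  ped <- data.frame(
    family_id = members$family_id,
    individual_id = members$individual_id,
    father_id = ifelse(is.na(members$father_id), "0", members$father_id),
    mother_id = ifelse(is.na(members$mother_id), "0", members$mother_id),
    sex_code = c(male = "1", female = "2", unknown = "0")[members$sex],
    aff_code = c(unaffected = "1", affected = "2", unknown = "0")[members$affection]
  )
  write.table(ped, ped_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  phen <- data.frame(
    family_id = members$family_id,
    individual_id = members$individual_id,
    affection = members$affection,
    cancer_type = ifelse(is.na(members$cancer_type), "", members$cancer_type),
    age = ifelse(is.na(members$age_dx_or_censor), "",
                 format(members$age_dx_or_censor, trim = TRUE)),
    is_sequenced = members$is_sequenced,
    is_index = members$is_index
  )
  write.table(phen, phenotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(list(ped_path = ped_path, phenotype_path = phenotype_path))
}
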