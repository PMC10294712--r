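# Cohort specification and session/image bookkeeping.
#
# A cohort spec is a list of strata. Each stratum contributes one PET session
# per subject (a subject x tracer x state combination), and every session
# yields exactly two images: an early (rest) and a late (challenge) phase.
# Linked strata (`subset_of`) reuse a subset of the subjects of a parent
# stratum, which is how repeat-scan designs (e.g. the same episodic
# migraineurs scanned interictally and ictally, or with both tracers) are
# encoded without inflating the subject count.

#' Cohort stratum
#'
#' @param tracer `"CFN"` or `"RCL"`.
#' @param group `"HC"`, `"EM"` or `"CM"`.
#' @param state `"none"` (controls), `"interictal"` or `"ictal"`.
#' @param n_subjects number of subjects scanned in this stratum.
#' @param n_female number of female subjects (rest male).
#' @param id stratum identifier (used by `subset_of`).
#' @param subset_of id of a parent stratum whose subjects this stratum reuses
#'   (the first `n_subjects` of the parent, a deterministic choice).
#' @return a `cohort_stratum` list.
#' @export
cohort_stratum <- function(tracer, group, state, n_subjects, n_female,
                           id = NULL, subset_of = NULL) {
  tracer <- match.arg(tracer, c("CFN", "RCL"))
  group <- match.arg(group, c("HC", "EM", "CM"))
  state <- match.arg(state, c("none", "interictal", "ictal"))
  stopifnot(n_subjects >= 0, n_female >= 0, n_female <= n_subjects)
  structure(list(tracer = tracer, group = group, state = state,
                 n_subjects = as.integer(n_subjects),
                 n_female = as.integer(n_female),
                 id = id %||% paste(tracer, group, state, sep = "_"),
                 subset_of = subset_of),
            class = "cohort_stratum")
}

#' Default two-tracer cohort specification
#'
#' Reproduces the study design this package emulates: 61 Carfentanil (CFN)
#' subjects -- 23 healthy controls, 7 chronic migraineurs scanned ictally,
#' 31 episodic migraineurs scanned interictally of whom 8 were also scanned
#' ictally -- and 22 Raclopride (RCL) subjects: 10 controls (a subset of the
#' CFN controls) and 12 of the episodic migraineurs scanned interictally, 8
#' of whom also ictally. Every session yields two images (early/late), so
#' the full spec produces 198 images: 138 CFN + 60 RCL.
#'
#' @param tracer `"both"` (default), `"CFN"` or `"RCL"` to restrict.
#' @return list of [cohort_stratum()] objects (class `cohort_spec`).
#' @export
default_cohort_spec <- function(tracer = c("both", "CFN", "RCL")) {
  tracer <- match.arg(tracer)
  strata <- list(
    cohort_stratum("CFN", "HC", "none", 23, 17, id = "CFN_HC"),
    cohort_stratum("CFN", "CM", "ictal", 7, 6, id = "CFN_CM_ictal"),
    cohort_stratum("CFN", "EM", "interictal", 31, 23, id = "CFN_EM_inter"),
    cohort_stratum("CFN", "EM", "ictal", 8, 4, id = "CFN_EM_ictal",
                   subset_of = "CFN_EM_inter"),
    cohort_stratum("RCL", "HC", "none", 10, 5, id = "RCL_HC",
                   subset_of = "CFN_HC"),
    cohort_stratum("RCL", "EM", "interictal", 12, 7, id = "RCL_EM_inter",
                   subset_of = "CFN_EM_inter"),
    cohort_stratum("RCL", "EM", "ictal", 8, 4, id = "RCL_EM_ictal",
                   subset_of = "RCL_EM_inter")
  )
  if (tracer != "both") {
    strata <- Filter(function(s) s$tracer == tracer, strata)
    # a restricted spec must not reference parents outside itself
    ids <- vapply(strata, `[[`, "", "id")
    strata <- lapply(strata, function(s) {
      if (!is.null(s$subset_of) && !(s$subset_of %in% ids)) s$subset_of <- NULL
      s
    })
  }
  structure(strata, class = "cohort_spec")
}

#' Generate the session and image tables for a cohort spec
#'
#' Subjects are assigned stable identifiers per parent stratum; linked strata
#' (`subset_of`) take the first n subjects of their parent so identities are
#' consistent across tracers and states. Sex is assigned within stratum
#' (females first) and is identical for a subject across strata.
#'
#' @param spec a `cohort_spec` (see [default_cohort_spec()]).
#' @param seed integer; reserved for future stochastic assignment, the
#'   default design is fully deterministic.
#' @return list with `sessions` (one row per subject x tracer x state) and
#'   `images` (two rows per session: phase `"early"`, `"late"`), both
#'   data.frames with columns subject_id, tracer, group, state, sex (+ phase,
#'   image_id for images).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec") || is.list(spec))
  roster <- list()  # stratum id -> data.frame(subject_id, sex)
  sessions <- list()
  for (s in spec) {
    if (!is.null(s$subset_of)) {
      parent <- roster[[s$subset_of]]
      if (is.null(parent)) {
        stop("generate_cohort: stratum '", s$id, "' references unknown parent '",
             s$subset_of, "'")
      }
      n_male <- s$n_subjects - s$n_female
      fem <- which(parent$sex == "F")
      mal <- which(parent$sex == "M")
      if (s$n_subjects > nrow(parent) || s$n_female > length(fem) ||
          n_male > length(mal)) {
        stop("generate_cohort: linked stratum '", s$id, "' needs ",
             s$n_female, "F + ", n_male, "M subjects but parent '",
             s$subset_of, "' has ", length(fem), "F + ", length(mal), "M")
      }
      # deterministic choice: the first n of each sex in the parent roster
      subs <- parent[c(fem[seq_len(s$n_female)], mal[seq_len(n_male)]), ,
                     drop = FALSE]
    } else {
      ids <- sprintf("%s%02d", gsub("_", "-", s$id), seq_len(s$n_subjects))
      sex <- c(rep("F", s$n_female), rep("M", s$n_subjects - s$n_female))
      subs <- data.frame(subject_id = ids, sex = sex,
                         stringsAsFactors = FALSE)
    }
    roster[[s$id]] <- subs
    if (s$n_subjects > 0) {
      sessions[[length(sessions) + 1L]] <- data.frame(
        subject_id = subs$subject_id, tracer = s$tracer, group = s$group,
        state = s$state, sex = subs$sex, stratum = s$id,
        stringsAsFactors = FALSE)
    }
  }
  sessions <- do.call(rbind, sessions)
  rownames(sessions) <- NULL
  images <- sessions[rep(seq_len(nrow(sessions)), each = 2L), , drop = FALSE]
  images$phase <- rep(c("early", "late"), times = nrow(sessions))
  images$image_id <- sprintf("%s_%s_%s_%s", images$subject_id, images$tracer,
                             images$state, images$phase)
  rownames(images) <- NULL
  list(sessions = sessions, images = images)
}

#' Summary counts for a generated cohort
#' @param cohort result of [generate_cohort()].
#' @return named list of subject and image counts per tracer and overall.
#' @export
cohort_counts <- function(cohort) {
  img <- cohort$images
  ses <- cohort$sessions
  n_subj <- function(tr) length(unique(ses$subject_id[ses$tracer == tr]))
  list(
    images_total = nrow(img),
    images_cfn = sum(img$tracer == "CFN"),
    images_rcl = sum(img$tracer == "RCL"),
    subjects_cfn = n_subj("CFN"),
    subjects_rcl = n_subj("RCL"),
    images_migraine = sum(img$group != "HC"),
    images_cfn_em_interictal = sum(img$tracer == "CFN" & img$group == "EM" &
                                     img$state == "interictal"),
    images_rcl_interictal = sum(img$tracer == "RCL" &
                                  img$state == "interictal"),
    images_cfn_interictal_only = sum(img$tracer == "CFN" &
                                       img$state != "ictal")
  )
}
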