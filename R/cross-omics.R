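#' Align transcript and protein identifier spaces
#'
#' Builds the one-to-one aligned universe over which the two screens can be
#' intersected. With `mapping = NULL` the identity mapping is used and the
#' universe is the intersection of the two id sets. Ids without a partner
#' are reported, never silently dropped.
#'
#' @param transcript_ids,protein_ids character vectors of feature ids.
#' @param mapping `NULL`, or a data frame with columns `transcript_id` and
#'   `protein_id`; duplicate ids on either side are an error.
#' @return list with `universe` (data frame `transcript_id`, `protein_id`),
#'   `unmapped_transcripts`, `unmapped_proteins`.
#' @export
map_ids <- function(transcript_ids, protein_ids, mapping = NULL) {
  if (is.null(mapping)) {
    common <- intersect(transcript_ids, protein_ids)
    mapping <- data.frame(transcript_id = common, protein_id = common,
                          stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(mapping$transcript_id) ||
        anyDuplicated(mapping$protein_id))
      stop("duplicate entries in the id mapping table", call. = FALSE)
    mapping <- mapping[mapping$transcript_id %in% transcript_ids &
                       mapping$protein_id %in% protein_ids, , drop = FALSE]
  }
  rownames(mapping) <- NULL
  list(universe = mapping,
       unmapped_transcripts = setdiff(transcript_ids,
                                      mapping$transcript_id),
       unmapped_proteins = setdiff(protein_ids, mapping$protein_id))
}

#' Intersect transcript and proteome hits into a candidate report
#'
#' A candidate must be flagged in the transcript consensus set and on every
#' proteome platform (`mode = "all_platforms"`, the default) or on at least
#' one (`mode = "any_platform"`), with the same direction in every
#' supporting screen when `require_direction` is `TRUE`; a candidate with
#' conflicting directions is never reported.
#'
#' @param transcript_hits data frame `feature_id`, `direction`, optionally
#'   `log2fc`.
#' @param proteome_hits a single hit data frame or a named list of them
#'   (one per platform), each with `feature_id`, `direction`, optionally
#'   `log2fc`.
#' @param mode `"all_platforms"` or `"any_platform"`.
#' @param require_direction demand direction agreement across all
#'   supporting screens.
#' @param mapping optional id mapping table for [map_ids()].
#' @return data frame `candidate_id`, `direction`, `transcript_log2fc` and
#'   one `log2fc`/`direction` pair per platform; zero rows is a valid
#'   outcome.
#' @export
intersect_candidates <- function(transcript_hits, proteome_hits,
                                 mode = c("all_platforms", "any_platform"),
                                 require_direction = TRUE,
                                 mapping = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(proteome_hits))
    proteome_hits <- list(platform1 = proteome_hits)
  if (is.null(names(proteome_hits)))
    names(proteome_hits) <- paste0("platform", seq_along(proteome_hits))
  prot_ids <- unique(unlist(lapply(proteome_hits, `[[`, "feature_id")))
  aligned <- map_ids(transcript_hits$feature_id, prot_ids, mapping)
  uni <- aligned$universe
  out <- data.frame(candidate_id = uni$transcript_id,
                    stringsAsFactors = FALSE)
  ti <- match(uni$transcript_id, transcript_hits$feature_id)
  out$direction <- transcript_hits$direction[ti]
  out$transcript_log2fc <- if ("log2fc" %in% names(transcript_hits))
    transcript_hits$log2fc[ti] else rep(NA_real_, nrow(out))
  on_platform <- matrix(FALSE, nrow(out), length(proteome_hits))
  agree <- rep(TRUE, nrow(out))
  for (j in seq_along(proteome_hits)) {
    ph <- proteome_hits[[j]]
    pi <- match(uni$protein_id, ph$feature_id)
    on_platform[, j] <- !is.na(pi)
    pdir <- ph$direction[pi]
    agree <- agree & (is.na(pdir) | pdir == out$direction)
    out[[paste0(names(proteome_hits)[j], "_log2fc")]] <-
      if ("log2fc" %in% names(ph)) ph$log2fc[pi]
      else rep(NA_real_, nrow(out))
    out[[paste0(names(proteome_hits)[j], "_direction")]] <- pdir
  }
  keep <- if (mode == "all_platforms") apply(on_platform, 1L, all)
          else apply(on_platform, 1L, any)
  if (require_direction) keep <- keep & agree
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped_transcripts") <- aligned$unmapped_transcripts
  attr(out, "unmapped_proteins") <- aligned$unmapped_proteins
  out
}
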