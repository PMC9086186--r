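#' Union of control-panel variant keys
#'
#' The "shared type" panel: every five-field key observed in any control
#' sample. Treated samples are filtered against this union.
#'
#' @param controls List of [sample_variant_set()] objects (>= 1).
#' @param ignore_geno Drop the genotype class from keys (see
#'   [variant_key()]).
#' @return Character vector of unique keys.
#' @export
control_shared_set <- function(controls, ignore_geno = FALSE) {
  stop_if_not(length(controls) >= 1, "control panel is empty")
  unique(unlist(lapply(controls, function(s) {
    variant_key(s$calls, ignore_geno = ignore_geno)
  }), use.names = FALSE))
}

#' Group-specific ("unique") variants of one sample
#'
#' Removes mutation types shared with the control panel. A treated sample
#' subtracts the full control-panel key union; a control sample, under
#' the default leave-one-out policy, subtracts the union of the *other*
#' controls' keys (so its own private calls survive). The alternative
#' `"group_intersection"` policy subtracts, from every sample, the keys
#' present in both the control union and the treated union.
#'
#' @param sample A [sample_variant_set()] with group set.
#' @param controls List of control [sample_variant_set()] objects.
#' @param policy `"leave_one_out"` (default behaviour described above),
#'   `"control_union"` (everyone subtracts the full control union,
#'   including controls themselves), or `"group_intersection"`.
#' @param treated For `policy = "group_intersection"` only: list of
#'   treated sample sets used to form the treated-union keys.
#' @param ignore_geno Match keys without the genotype class.
#' @return A [sample_variant_set()] holding the surviving calls;
#'   `group` and `clean_bases` are carried over unchanged.
#' @export
group_specific_variants <- function(sample, controls,
                                    policy = c("leave_one_out",
                                               "control_union",
                                               "group_intersection"),
                                    treated = NULL, ignore_geno = FALSE) {
  policy <- match.arg(policy)
  stop_if_not(inherits(sample, "sample_variant_set"),
              "sample must be a sample_variant_set")
  stop_if_not(!is.na(sample$group), "sample group must be set before filtering")
  is_control <- identical(sample$group, "control")

  remove_keys <- switch(policy,
    leave_one_out = {
      if (is_control) {
        others <- Filter(function(s) s$sample_id != sample$sample_id, controls)
        if (length(others) == 0) character(0)
        else control_shared_set(others, ignore_geno)
      } else {
        control_shared_set(controls, ignore_geno)
      }
    },
    control_union = control_shared_set(controls, ignore_geno),
    group_intersection = {
      stop_if_not(!is.null(treated),
                  "policy 'group_intersection' needs the treated sample list")
      cu <- control_shared_set(controls, ignore_geno)
      tu <- control_shared_set(treated, ignore_geno)
      intersect(cu, tu)
    })

  keep <- !(variant_key(sample$calls, ignore_geno) %in% remove_keys)
  out <- sample$calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  sample_variant_set(out, sample$sample_id, sample$group, sample$clean_bases)
}

#' Shared-type filtering across a whole cohort
#'
#' Applies [group_specific_variants()] to every sample of a cohort.
#'
#' @param cohort Named list of [sample_variant_set()] objects.
#' @inheritParams group_specific_variants
#' @return Named list of filtered `sample_variant_set` objects, same order.
#' @export
filter_shared <- function(cohort, policy = "leave_one_out",
                          ignore_geno = FALSE) {
  groups <- vapply(cohort, function(s) s$group, character(1))
  stop_if_not(!anyNA(groups), "all samples need a group label")
  controls <- cohort[groups == "control"]
  treated <- cohort[groups != "control"]
  stop_if_not(length(controls) >= 1, "cohort has no control samples")
  lapply(cohort, group_specific_variants, controls = controls,
         policy = policy, treated = treated, ignore_geno = ignore_geno)
}
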