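# Seeded organ-allocation simulator. A waiting list of NW recipients is
# drawn from a candidate pool; donors stream in one at a time; each policy
# (survival-model ranking, criterion-based clinical tiers, or random
# control) matches the donor to at most one ABO-compatible recipient, the
# matched pair's predicted median survival is recorded, and the matched
# recipient is replaced by a fresh recipient from the pool. By default all
# policies share the donor and replacement random-number streams (common
# random numbers), so policy differences are not sampling noise; a
# paper-faithful mode that randomizes one policy per donor is also
# available.

ABO_COMPATIBLE <- list(
  O = c("O", "A", "B", "AB"),
  A = c("A", "AB"),
  B = c("B", "AB"),
  AB = "AB"
)

#' ABO blood-group compatibility
#'
#' Standard donor-to-recipient rules: O is the universal donor, AB the
#' universal recipient.
#'
#' @param donor_bg,recipient_bg Blood-group labels among A, AB, B, O
#'   (vectorized; recycled).
#' @return Logical vector.
#' @export
#' @examples
#' abo_compatible("O", "A") # TRUE
#' abo_compatible("AB", "O") # FALSE
abo_compatible <- function(donor_bg, recipient_bg) {
  bad <- setdiff(unique(c(donor_bg, recipient_bg)), BLOOD_GROUPS)
  if (length(bad) > 0) {
    abort(paste0("invalid blood group: ", paste(bad, collapse = ", ")),
      class = "ihtsa_argument_error"
    )
  }
  mapply(function(d, r) r %in% ABO_COMPATIBLE[[d]], donor_bg, recipient_bg,
    USE.NAMES = FALSE
  )
}

#' Clinical matching priority tier
#'
#' Criterion-based clinical allocation: a recipient is eligible iff the
#' donor is ABO-compatible and the donor weight is within +/-20% of the
#' recipient weight; if the recipient's PVR exceeds 3.0 Wood units the donor
#' must additionally be 0-15% heavier than the recipient and female-to-male
#' donation is excluded. Eligible matches are tiered: 1 = identical blood
#' group and both ages <= 35; 2 = identical group and donor age < recipient
#' age + 15; 3 = any remaining eligible match. Missing required fields make
#' the recipient ineligible (reason recorded).
#'
#' @param donor One-row list/tibble with `donor_bg`, `donor_age`,
#'   `donor_weight`, `donor_sex`.
#' @param recipient One-row list/tibble with `recipient_bg`,
#'   `recipient_age`, `recipient_weight`, `recipient_sex`, `pvr`.
#' @return Integer tier 1-3, or `NA` (ineligible) with attribute `"reason"`.
#' @export
clinical_priority <- function(donor, recipient) {
  need_d <- c("donor_bg", "donor_age", "donor_weight", "donor_sex")
  need_r <- c("recipient_bg", "recipient_age", "recipient_weight", "recipient_sex", "pvr")
  vals_d <- lapply(need_d, function(f) donor[[f]])
  vals_r <- lapply(need_r, function(f) recipient[[f]])
  if (any(vapply(c(vals_d, vals_r), function(v) is.null(v) || is.na(v), logical(1)))) {
    out <- NA_integer_
    attr(out, "reason") <- "missing required field"
    return(out)
  }
  if (!abo_compatible(donor$donor_bg, recipient$recipient_bg)) {
    out <- NA_integer_
    attr(out, "reason") <- "ABO incompatible"
    return(out)
  }
  rw <- recipient$recipient_weight
  dw <- donor$donor_weight
  if (abs(dw - rw) > 0.20 * rw) {
    out <- NA_integer_
    attr(out, "reason") <- "weight outside +/-20%"
    return(out)
  }
  if (recipient$pvr > 3.0) {
    if (dw < rw || dw > 1.15 * rw) {
      out <- NA_integer_
      attr(out, "reason") <- "PVR > 3: donor weight outside 0-15% above recipient"
      return(out)
    }
    if (donor$donor_sex == "female" && recipient$recipient_sex == "male") {
      out <- NA_integer_
      attr(out, "reason") <- "PVR > 3: female-to-male donation excluded"
      return(out)
    }
  }
  identical_bg <- donor$donor_bg == recipient$recipient_bg
  if (identical_bg && donor$donor_age <= 35 && recipient$recipient_age <= 35) {
    return(1L)
  }
  if (identical_bg && donor$donor_age < recipient$recipient_age + 15) {
    return(2L)
  }
  3L
}

# Substitute the donor's fields into every candidate recipient row and
# recompute the derived ratios; ischemia time is unknown before transplant
# and set to the pool median.
hypothetical_pairs <- function(waitlist, donor, ischemia_default) {
  out <- waitlist
  out$donor_age <- donor$donor_age
  out$donor_sex <- donor$donor_sex
  out$donor_weight <- donor$donor_weight
  out$donor_bg <- donor$donor_bg
  out$codd_head_trauma <- donor$codd_head_trauma
  out$codd_cva <- donor$codd_cva
  out$ischemia_min <- ischemia_default
  out
}

#' Allocate one donor under a policy
#'
#' Chooses at most one recipient from the waiting list: the model policy
#' takes the ABO-compatible candidate whose hypothetical pairing with this
#' donor has the largest predicted median survival; the clinical policy
#' takes the lowest tier number (ties by a seeded uniform draw); the random
#' control draws uniformly among ABO-compatible candidates.
#'
#' @param donor One-row tibble of donor fields.
#' @param waitlist Tibble of candidate recipients (complete cohort rows).
#' @param policy `"ihtsa"`, `"clinical"` or `"random"`.
#' @param model An `ihtsa_ensemble` (required for `"ihtsa"`).
#' @param ischemia_default Ischemia minutes assumed for hypothetical pairs.
#' @param tie_u A uniform deviate in [0, 1) used for tie-breaking /random
#'   selection (supplied by the simulation's policy stream).
#' @return A list: `index` (row in `waitlist`, or `NA` when no candidate is
#'   eligible) and `predicted_median` (for the matched pair; `NA` for none).
#' @export
allocate_donor <- function(donor, waitlist, policy, model = NULL,
                           ischemia_default = 183, tie_u = 0.5) {
  compatible <- which(abo_compatible(
    rep(donor$donor_bg, nrow(waitlist)),
    waitlist$recipient_bg
  ))
  if (length(compatible) == 0) {
    return(list(index = NA_integer_, predicted_median = NA_real_))
  }
  pairs <- hypothetical_pairs(
    waitlist[compatible, , drop = FALSE], donor, ischemia_default
  )
  pick <- switch(policy,
    ihtsa = {
      if (is.null(model)) {
        abort("ihtsa policy requires a trained ensemble",
          class = "ihtsa_argument_error"
        )
      }
      med <- predicted_median_survival(model, pairs)$median_years
      best <- which(med == max(med))
      if (length(best) > 1) best <- best[floor(tie_u * length(best)) + 1]
      compatible[best]
    },
    clinical = {
      tiers <- vapply(seq_len(nrow(pairs)), function(i) {
        as.integer(clinical_priority(
          pairs[i, , drop = FALSE], pairs[i, , drop = FALSE]
        ))
      }, integer(1))
      if (all(is.na(tiers))) {
        NA_integer_
      } else {
        best <- which(tiers == min(tiers, na.rm = TRUE))
        if (length(best) > 1) best <- best[floor(tie_u * length(best)) + 1]
        compatible[best]
      }
    },
    random = {
      compatible[floor(tie_u * length(compatible)) + 1]
    },
    abort(paste0("unknown policy ", policy), class = "ihtsa_argument_error")
  )
  if (is.na(pick)) {
    return(list(index = NA_integer_, predicted_median = NA_real_))
  }
  med <- if (!is.null(model)) {
    pair <- hypothetical_pairs(
      waitlist[pick, , drop = FALSE], donor, ischemia_default
    )
    predicted_median_survival(model, pair)$median_years
  } else {
    NA_real_
  }
  list(index = pick, predicted_median = med)
}

#' Run the allocation simulation
#'
#' Draws a seeded waiting list of `nw` recipients from the pool, then
#' streams `n_donor_draws` donors sampled (with replacement) from the pool's
#' donor fields. A donor with at least one ABO-compatible recipient on the
#' list is offered to every requested policy, each running on its own copy
#' of the list; matched recipients are replaced from the pool's remaining
#' recipients. Under `crn = TRUE` (default) the donor stream, the
#' replacement stream, and the initial list are common across policies and
#' only the tie-break streams differ; `crn = FALSE` randomizes one policy
#' per donor as in registry practice.
#'
#' @param pool A complete cohort tibble (larger than `nw`).
#' @param nw Waiting-list size.
#' @param n_donor_draws Number of donor arrivals to simulate.
#' @param policies Character vector among `"ihtsa"`, `"clinical"`,
#'   `"random"`.
#' @param model An `ihtsa_ensemble` (needed when `"ihtsa"` is requested;
#'   also used to record predicted survival of every policy's matches).
#' @param seed Integer seed.
#' @param crn Use common random numbers across policies (default `TRUE`).
#' @return An `ihtsa_allocation_run`: `summary` (per-policy tibble with
#'   `transplants`, `offers`, `refusals`, `mean_predicted_median`),
#'   `matches` (per-match tibble: policy, draw, donor row, recipient pool
#'   row, predicted median), `nw`, `n_donor_draws`, `seed`, `crn`.
#' @export
run_simulation <- function(pool, nw, n_donor_draws, policies = c("ihtsa", "clinical", "random"),
                           model = NULL, seed = 1, crn = TRUE) {
  if (nrow(pool) <= nw) {
    abort("pool must be larger than the waiting list", class = "ihtsa_argument_error")
  }
  if ("ihtsa" %in% policies && is.null(model)) {
    abort("ihtsa policy requires a model", class = "ihtsa_argument_error")
  }
  n_pool <- nrow(pool)
  ischemia_default <- median(pool$ischemia_min, na.rm = TRUE)
  streams <- with_seed(seed_stream(seed, "alloc"), {
    list(
      init = sample.int(n_pool, nw),
      donors = sample.int(n_pool, n_donor_draws, replace = TRUE),
      replacement_order = sample.int(n_pool),
      policy_pick = sample.int(length(policies), n_donor_draws, replace = TRUE)
    )
  })
  tie_streams <- lapply(policies, function(p) {
    with_seed(seed_stream(seed, paste0("tie_", p)), runif(n_donor_draws))
  })
  names(tie_streams) <- policies
  run_policy <- function(policy, donor_subset = NULL) {
    list_rows <- streams$init
    used <- rep(FALSE, n_pool)
    used[list_rows] <- TRUE
    repl_queue <- setdiff(streams$replacement_order, list_rows)
    matches <- list()
    offers <- 0
    refusals <- 0
    truncated <- FALSE
    draws <- donor_subset %||% seq_len(n_donor_draws)
    for (dr in draws) {
      donor_row <- streams$donors[dr]
      donor <- pool[donor_row, , drop = FALSE]
      waitlist <- pool[list_rows, , drop = FALSE]
      if (!any(abo_compatible(
        rep(donor$donor_bg, nrow(waitlist)), waitlist$recipient_bg
      ))) {
        next
      }
      offers <- offers + 1
      res <- allocate_donor(donor, waitlist, policy,
        model = model,
        ischemia_default = ischemia_default,
        tie_u = tie_streams[[policy]][dr]
      )
      if (is.na(res$index)) {
        refusals <- refusals + 1
        next
      }
      matched_pool_row <- list_rows[res$index]
      matches[[length(matches) + 1]] <- tibble(
        policy = policy, draw = dr, donor_row = donor_row,
        recipient_row = matched_pool_row,
        predicted_median = res$predicted_median
      )
      if (length(repl_queue) == 0) {
        truncated <- TRUE
        warn(paste0("pool exhausted for replacements (policy ", policy, "); run truncated"))
        list_rows <- list_rows[-res$index]
        if (length(list_rows) == 0) break
      } else {
        list_rows[res$index] <- repl_queue[1]
        repl_queue <- repl_queue[-1]
      }
    }
    list(
      matches = if (length(matches)) dplyr::bind_rows(matches) else tibble(),
      offers = offers, refusals = refusals, truncated = truncated
    )
  }
  results <- if (crn) {
    lapply(policies, function(p) run_policy(p))
  } else {
    lapply(seq_along(policies), function(pi) {
      run_policy(policies[pi], donor_subset = which(streams$policy_pick == pi))
    })
  }
  names(results) <- policies
  matches <- dplyr::bind_rows(lapply(results, `[[`, "matches"))
  summary <- purrr::map_dfr(policies, function(p) {
    m <- results[[p]]$matches
    tibble(
      policy = p,
      offers = results[[p]]$offers,
      transplants = nrow(m),
      refusals = results[[p]]$refusals,
      mean_predicted_median = if (nrow(m) > 0 && !all(is.na(m$predicted_median))) {
        mean(m$predicted_median, na.rm = TRUE)
      } else {
        NA_real_
      }
    )
  })
  structure(
    list(
      summary = summary, matches = matches, nw = nw,
      n_donor_draws = n_donor_draws, seed = seed, crn = crn,
      policies = policies
    ),
    class = "ihtsa_allocation_run"
  )
}

#' @export
print.ihtsa_allocation_run <- function(x, ...) {
  cat(
    "<ihtsa_allocation_run> nw = ", x$nw, ", ", x$n_donor_draws,
    " donor draws", if (x$crn) " (common random numbers)", "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Filter high-risk candidates from an allocation pool
#'
#' @param pool A cohort tibble.
#' @param exclude A predicate function `f(pool) -> logical` marking records
#'   to drop (default: ICU, ventilator, ECMO or VAD).
#' @return The filtered pool (error when empty).
#' @export
sensitivity_filter <- function(pool, exclude = NULL) {
  drop <- if (is.null(exclude)) {
    with(pool, icu == 1 | ventilator == 1 | ecmo == 1 | vad == 1)
  } else {
    exclude(pool)
  }
  drop[is.na(drop)] <- FALSE
  out <- pool[!drop, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("sensitivity filter removed every record", class = "ihtsa_argument_error")
  }
  out
}
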