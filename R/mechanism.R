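# Discrete-state simulator of the hypothetical ten-state electron
# bifurcation cycle. The model is a reversible state machine with exact
# electron bookkeeping and no kinetics: legality of each event is decided
# from the state content (flavin redox state, cluster occupancy,
# conformation, bound ligands), and every event has an exact inverse.
#
# Conformational gating: the C1-B2 edge (19 A apart in the open resting
# enzyme, 13 A in the NAD(H)-bound closed form) only transfers electrons
# in the closed conformation, which is entered and left together with
# NAD(H) binding and release.

OPEN_C1_B2_ANGSTROM <- 19
CLOSED_C1_B2_ANGSTROM <- 13
MAX_TRANSFER_ANGSTROM <- 13

CLUSTERS <- c("B1", "B2", "B3", "B4", "B5", "C1")
RELAY_ORDER <- c("B1", "C1", "B5")  # FMN is the entry conduit

fmn_electrons <- c(OX = 0L, SQ = 1L, HQ = 2L)

new_state <- function(fmn, occ_on = character(), conformation = "open",
                      bound = character(), tallies = NULL) {
  occ <- stats::setNames(integer(length(CLUSTERS)), CLUSTERS)
  occ[occ_on] <- 1L
  if (is.null(tallies)) {
    # net counters so that every event cancels its inverse exactly;
    # the consumed/produced view is derived by mech_tallies()
    tallies <- c(H2_net = 0L, H_plus_net = 0L, NADH_net = 0L,
                 Fd_red_net = 0L)
  }
  structure(list(fmn = fmn, occ = occ, conformation = conformation,
                 bound = sort(bound), tallies = tallies),
            class = "mech_state")
}

#' Core electron count of a mechanism state
#' @param state A `mech_state`.
#' @return FMN electrons (OX=0, SQ=1, HQ=2) plus cluster occupancy.
#' @export
core_electrons <- function(state) {
  unname(fmn_electrons[state$fmn]) + sum(state$occ)
}

bound_electrons <- function(state) {
  2L * as.integer("Fd_red" %in% state$bound)
}

#' Substrate tallies of a mechanism state
#'
#' Reports the net substrate turnover since the tallies were zeroed:
#' `H2_consumed`/`H2_produced` (derived from the net H2 count, so a
#' forward step followed by its inverse cancels exactly), `H_plus_net`,
#' `NADH_net` and `Fd_red_net` (positive = released).
#'
#' @param state A `mech_state`.
#' @return Named integer vector.
#' @export
mech_tallies <- function(state) {
  t <- state$tallies
  c(H2_consumed = max(t[["H2_net"]], 0L),
    H2_produced = max(-t[["H2_net"]], 0L),
    H_plus_net = t[["H_plus_net"]],
    NADH_net = t[["NADH_net"]],
    Fd_red_net = t[["Fd_red_net"]])
}

#' The canonical ten-state table of the bifurcation cycle
#'
#' State 1 is the fully oxidized resting enzyme; states 2-6 load four
#' mid-potential electrons through the FMN conduit onto B1, C1 and B5;
#' state 7 is the NAD+-bound closed form with the low-potential pair on
#' C1 and B2; states 8-10 reduce and release Fd and form NADH.
#'
#' @return List of ten `mech_state` objects (tallies zeroed).
#' @export
mech_states <- function() {
  list(
    new_state("OX"),
    new_state("HQ"),
    new_state("SQ", "B1"),
    new_state("OX", c("B1", "C1")),
    new_state("HQ", c("B1", "C1")),
    new_state("SQ", c("B1", "C1", "B5")),
    new_state("SQ", c("B1", "B2", "C1"), "closed", "NAD"),
    new_state("SQ", "B1", "closed", c("Fd_red", "NAD")),
    new_state("SQ", "B1", "closed", "NAD"),
    new_state("HQ", character(), "closed", "NAD")
  )
}

#' Index of a state in the canonical cycle
#' @param state A `mech_state`.
#' @return Integer 1..10, or NA for a non-canonical state.
#' @export
state_index <- function(state) {
  for (i in seq_along(canon <- mech_states())) {
    s <- canon[[i]]
    if (identical(s$fmn, state$fmn) && all(s$occ == state$occ) &&
        identical(s$conformation, state$conformation) &&
        identical(s$bound, state$bound)) {
      return(i)
    }
  }
  NA_integer_
}

#' The resting enzyme state
#'
#' State 1: fully oxidized "0 e-" form, open conformation, nothing bound,
#' all tallies zero.
#' @return A `mech_state`.
#' @export
initial_state <- function() new_state("OX")

MECH_EVENTS <- c("oxidize_H2", "relay_electron", "bind_NAD", "reduce_Fd",
                 "release_Fd_red", "b1_to_fmn", "release_NADH",
                 "produce_H2", "relay_back", "release_NAD",
                 "oxidize_Fd_red", "bind_Fd_red", "fmn_to_b1", "bind_NADH")

INVERSE_EVENT <- c(
  oxidize_H2 = "produce_H2", produce_H2 = "oxidize_H2",
  relay_electron = "relay_back", relay_back = "relay_electron",
  bind_NAD = "release_NAD", release_NAD = "bind_NAD",
  reduce_Fd = "oxidize_Fd_red", oxidize_Fd_red = "reduce_Fd",
  release_Fd_red = "bind_Fd_red", bind_Fd_red = "release_Fd_red",
  b1_to_fmn = "fmn_to_b1", fmn_to_b1 = "b1_to_fmn",
  release_NADH = "bind_NADH", bind_NADH = "release_NADH")

#' Inverse of a mechanism event
#' @param event Event name.
#' @return The inverse event name.
#' @export
inverse_event <- function(event) {
  if (!event %in% names(INVERSE_EVENT)) stop("unknown event: ", event)
  unname(INVERSE_EVENT[event])
}

# Legality: returns NULL (legal) or a reason string.
event_illegal_reason <- function(state, event) {
  open <- state$conformation == "open"
  nad <- "NAD" %in% state$bound
  fd <- "Fd_red" %in% state$bound
  occ <- state$occ
  relay_target <- RELAY_ORDER[which(occ[RELAY_ORDER] == 0L)[1]]
  relay_source <- rev(RELAY_ORDER)[which(occ[rev(RELAY_ORDER)] == 1L)[1]]
  switch(event,
    oxidize_H2 = if (!open) "requires open conformation"
      else if (state$fmn != "OX") "FMN must be oxidized to accept 2 e-",
    produce_H2 = if (!open) "requires open conformation"
      else if (state$fmn != "HQ") "FMN must hold 2 e-",
    relay_electron = if (!open) "requires open conformation"
      else if (fmn_electrons[state$fmn] < 1) "no electron on FMN"
      else if (is.na(relay_target)) "no free relay cluster",
    relay_back = if (!open) "requires open conformation"
      else if (state$fmn == "HQ") "FMN full"
      else if (is.na(relay_source)) "no occupied relay cluster",
    bind_NAD = if (!open) "already closed"
      else if (nad) "NAD already bound"
      else if (!(state$fmn == "SQ" && all(occ[c("B1", "C1", "B5")] == 1L)))
        "requires the 4 e- loaded arrangement (SQ, B1, C1, B5)",
    release_NAD = if (open || !nad) "NAD not bound"
      else if (fd) "Fd still bound"
      else if (!(all(occ[c("B1", "B2", "C1")] == 1L) && state$fmn == "SQ"))
        "low-potential pair not on B2/C1",
    reduce_Fd = if (open) "open conformation: C1-B2 gap (19 A) precludes transfer"
      else if (!nad) "NAD not bound"
      else if (fd) "Fd already bound"
      else if (!all(occ[c("B2", "C1")] == 1L)) "low-potential pair missing",
    oxidize_Fd_red = if (!fd) "no Fd_red bound"
      else if (any(occ[c("B2", "C1")] == 1L)) "B2/C1 already occupied",
    release_Fd_red = if (!fd) "no Fd_red bound",
    bind_Fd_red = if (open) "requires closed conformation"
      else if (!nad) "NAD not bound"
      else if (fd) "Fd already bound"
      else if (any(occ[c("B2", "C1")] == 1L)) "B2/C1 occupied"
      else if (!(state$fmn == "SQ" && occ["B1"] == 1L)) "not the post-Fd state",
    b1_to_fmn = if (open) "requires closed conformation"
      else if (!nad) "NAD not bound"
      else if (fd) "Fd still bound"
      else if (!(state$fmn == "SQ" && occ["B1"] == 1L &&
                   all(occ[c("B2", "C1", "B5")] == 0L)))
        "requires SQ with B1 only",
    fmn_to_b1 = if (open) "requires closed conformation"
      else if (!nad) "NAD not bound"
      else if (fd) "Fd still bound"
      else if (!(state$fmn == "HQ" && sum(occ) == 0L)) "requires HQ, clusters empty",
    release_NADH = if (open || !nad) "NAD not bound"
      else if (fd) "Fd still bound"
      else if (!(state$fmn == "HQ" && sum(occ) == 0L))
        "hydride not assembled on FMN",
    bind_NADH = if (!open) "already closed"
      else if (nad) "NAD already bound"
      else if (!(state$fmn == "OX" && sum(occ) == 0L)) "enzyme not fully oxidized",
    stop("unknown event: ", event)
  )
}

#' Legal events in a state
#' @param state A `mech_state`.
#' @return Character vector of legal event names.
#' @export
legal_events <- function(state) {
  MECH_EVENTS[vapply(MECH_EVENTS, function(e)
    is.null(event_illegal_reason(state, e)), logical(1))]
}

#' Apply an event to a mechanism state
#'
#' Occupancy, conformation, bound ligands and tallies are updated; an
#' illegal event is rejected with an error naming the state and the
#' reason. Electron transfer across the C1-B2 edge only happens in the
#' closed conformation (distance gate at 13 A).
#'
#' @param state A `mech_state`.
#' @param event Event name (see `legal_events()`).
#' @return The new `mech_state`.
#' @export
apply_event <- function(state, event) {
  reason <- event_illegal_reason(state, event)
  if (!is.null(reason)) {
    stop("illegal event '", event, "' in state ",
         state_index(state), ": ", reason)
  }
  s <- state
  bump <- function(key, by) s$tallies[key] <<- s$tallies[key] + by
  switch(event,
    oxidize_H2 = { s$fmn <- "HQ"; bump("H2_net", 1L)
                   bump("H_plus_net", 2L) },
    produce_H2 = { s$fmn <- "OX"; bump("H2_net", -1L)
                   bump("H_plus_net", -2L) },
    relay_electron = {
      target <- RELAY_ORDER[which(s$occ[RELAY_ORDER] == 0L)[1]]
      s$occ[target] <- 1L
      s$fmn <- names(fmn_electrons)[fmn_electrons == fmn_electrons[s$fmn] - 1L]
    },
    relay_back = {
      source <- rev(RELAY_ORDER)[which(s$occ[rev(RELAY_ORDER)] == 1L)[1]]
      s$occ[source] <- 0L
      s$fmn <- names(fmn_electrons)[fmn_electrons == fmn_electrons[s$fmn] + 1L]
    },
    bind_NAD = { s$bound <- sort(c(s$bound, "NAD"))
                 s$conformation <- "closed"
                 s$occ["B5"] <- 0L; s$occ["B2"] <- 1L },  # low pair to B2/C1
    release_NAD = { s$bound <- setdiff(s$bound, "NAD")
                    s$conformation <- "open"
                    s$occ["B2"] <- 0L; s$occ["B5"] <- 1L },
    reduce_Fd = { s$occ[c("B2", "C1")] <- 0L
                  s$bound <- sort(c(s$bound, "Fd_red")) },
    oxidize_Fd_red = { s$occ[c("B2", "C1")] <- 1L
                       s$bound <- setdiff(s$bound, "Fd_red") },
    release_Fd_red = { s$bound <- setdiff(s$bound, "Fd_red")
                       bump("Fd_red_net", 1L) },
    bind_Fd_red = { s$bound <- sort(c(s$bound, "Fd_red"))
                    bump("Fd_red_net", -1L) },
    b1_to_fmn = { s$occ["B1"] <- 0L; s$fmn <- "HQ" },
    fmn_to_b1 = { s$occ["B1"] <- 1L; s$fmn <- "SQ" },
    release_NADH = { s$fmn <- "OX"; s$bound <- setdiff(s$bound, "NAD")
                     s$conformation <- "open"
                     bump("NADH_net", 1L); bump("H_plus_net", -1L) },
    bind_NADH = { s$fmn <- "HQ"; s$bound <- sort(c(s$bound, "NAD"))
                  s$conformation <- "closed"
                  bump("NADH_net", -1L); bump("H_plus_net", 1L) }
  )
  s
}

CANONICAL_FORWARD <- c("oxidize_H2", "relay_electron", "relay_electron",
                       "oxidize_H2", "relay_electron", "bind_NAD",
                       "reduce_Fd", "release_Fd_red", "b1_to_fmn",
                       "release_NADH")

#' Run one canonical catalytic cycle
#'
#' Bifurcation runs state 1 through 10 and back to 1, consuming two H2 and
#' producing one NADH and one reduced Fd (with three protons released);
#' confurcation is the exact reverse.
#'
#' @param direction `"bifurcation"` or `"confurcation"`.
#' @param state Starting state (default the resting enzyme).
#' @return A `mech_trajectory`: list with `steps` (data.frame: step,
#'   state_index, event), `states`, `final`, `net` (tally vector).
#' @export
run_cycle <- function(direction = c("bifurcation", "confurcation"),
                      state = initial_state()) {
  direction <- match.arg(direction)
  events <- if (direction == "bifurcation") {
    CANONICAL_FORWARD
  } else {
    rev(vapply(CANONICAL_FORWARD, inverse_event, ""))
  }
  states <- list(state)
  for (e in events) state <- apply_event(state, e)
  for (k in seq_along(events)) {
    states[[k + 1]] <- Reduce(apply_event, events[seq_len(k)], states[[1]])
  }
  idx <- vapply(states, state_index, integer(1))
  steps <- data.frame(step = seq_along(events),
                      from_state = idx[-length(idx)],
                      to_state = idx[-1],
                      event = events, stringsAsFactors = FALSE)
  structure(list(steps = steps, states = states, final = state,
                 net = mech_tallies(state), direction = direction),
            class = "mech_trajectory")
}

#' Is electron transfer possible at a given edge distance?
#'
#' @param distance_angstrom Positive center-to-center distance.
#' @return TRUE iff the distance is within electron transfer range
#'   (<= 13 Angstrom).
#' @export
transfer_allowed <- function(distance_angstrom) {
  if (distance_angstrom <= 0) stop("distance must be positive")
  distance_angstrom <= MAX_TRANSFER_ANGSTROM
}
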