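#' Standard 64-channel 10/20 EEG montage
#'
#' Electrode labels for a 64-channel active-electrode cap in the extended
#' 10/20 system (the layout used by common 64-channel actiCAP-style systems,
#' recorded against Cz and re-referenced offline).
#'
#' @return Character vector of 64 channel labels.
#' @export
#' @examples
#' head(eeg_montage())
eeg_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8",
    "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FCz", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6",
    "PO7", "PO3", "PO4", "PO8")
}

#' Scalp region groups of the 64-channel montage
#'
#' Named channel groups used to place simulated ERP components and to read
#' stability reports: the groups match the regions conventionally reported
#' for the N170 (occipito-parietal), P200/N400 (frontal and fronto-central)
#' and LPC (centro-parietal and parietal).
#'
#' @return Named list of character vectors, each a subset of [eeg_montage()].
#' @export
channel_groups <- function() {
  list(
    frontal          = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
                         "AF7", "AF3", "AF4", "AF8"),
    fronto_central   = c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6"),
    central          = c("C5", "C3", "C1", "Cz", "C2", "C4", "C6"),
    centro_parietal  = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"),
    parietal         = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    occipito_parietal = c("P7", "P8", "PO7", "PO3", "PO4", "PO8", "PO9",
                          "PO10", "O1", "Oz", "O2"),
    occipital        = c("O1", "Oz", "O2")
  )
}
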