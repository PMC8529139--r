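# liu2021_mir21: exosomal miR-21 diagnostic accuracy study set

30 trials from 26 published articles (2008–2020) evaluating exosomal
microRNA-21 as a diagnostic biomarker for cancer. Each row is one trial's
2x2 confusion table (`tp`, `fn`, `fp`, `tn`) against a gold-standard cancer
diagnosis, plus study metadata. For every row
`tp + fn + fp + tn == sample_size`.

Articles contributing several trials (distinct patient strata or blood
compartments) appear as multiple rows sharing an `article_id`
(Goto2018: IPMN / early PC / advanced PC; Kawamura2018: portal-vein /
peripheral blood; Liu2020: two serum cohorts). All pooling treats trials as
independent units.

## Column-labelling note

In the published source table the two middle count columns are headed
"FN, FP", but the counts only reproduce that article's own pooled results
(sensitivity 0.76, specificity 0.82) and its positive-predictive-value tally
(PPV > 0.75 in 23 of 30 trials) when those two columns are read in the
order FP, FN — i.e. the printed headers are transposed. This file stores
the corrected labelling. Under the printed labelling the pooled estimates
come out transposed-looking (Se 0.86, Sp 0.73) and the PPV tally is 14/30.

## Derived grouping columns

The source article states subgroup sizes without enumerating membership;
the mapping below is materialized as fixture columns so analyses are
reproducible.

- `ethnicity_group`: `caucasian` for trials run in the United States,
  Canada, Spain and Germany (9 trials); `asian` for Japan and China (21).
- `sample_group`: `plasma` / `serum` taken from the Source column
  (6 and 15 trials); `other` for urine, CSF, pancreatic juice, cyst/lavage
  fluids, portal-vein and peripheral blood (9). The source article's prose
  says "serum (n = 13)" but omits urine and CSF from its tally and its
  source counts do not sum to 30; the Source column is authoritative here.
- `cancer_group`: `breast` (2), `lung` (3), `other` (11: the source's
  enumerated list — colon cancer, ovarian, hepatocellular, glioma, renal
  cell, IPMN, lymphoma — plus urothelial and laryngeal carcinoma),
  `digestive` (the remaining 14). The source claims a 13/11
  digestive/other split, but its four group sizes sum to 29, not 30; this
  is one defensible completion and is flagged as such.
- `pancreatic`: `TRUE` for PC, PDAC and IPMN trials (8 rows).
- `cutoff`: the trial's positivity threshold as free text; never used in
  computation.
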