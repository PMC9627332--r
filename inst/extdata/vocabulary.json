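{
  "ingredient_map": {
    "ZOMETA": "zoledronic acid",
    "RECLAST": "zoledronic acid",
    "ZOLEDRONIC ACID": "zoledronic acid",
    "ZOLEDRONATE": "zoledronic acid",
    "FOSAMAX": "alendronate",
    "ALENDRONATE": "alendronate",
    "ALENDRONATE SODIUM": "alendronate",
    "ALENDRONIC ACID": "alendronate",
    "ACTONEL": "risedronate",
    "RISEDRONATE": "risedronate",
    "RISEDRONATE SODIUM": "risedronate",
    "RISEDRONIC ACID": "risedronate",
    "BONIVA": "ibandronate",
    "BONDRONAT": "ibandronate",
    "IBANDRONATE": "ibandronate",
    "IBANDRONIC ACID": "ibandronate",
    "XGEVA": "denosumab",
    "PROLIA": "denosumab",
    "DENOSUMAB": "denosumab",
    "EVENITY": "romosozumab",
    "ROMOSOZUMAB": "romosozumab",
    "AREDIA": "pamidronate",
    "PAMIDRONATE": "pamidronate",
    "PAMIDRONATE DISODIUM": "pamidronate",
    "PAMIDRONIC ACID": "pamidronate",
    "DIDRONEL": "etidronate",
    "ETIDRONATE": "etidronate",
    "ETIDRONIC ACID": "etidronate"
  },
  "pt_to_hlt": {
    "osteoporosis": "metabolic bone disorders",
    "osteoporosis postmenopause": "metabolic bone disorders",
    "postmenopause": "metabolic bone disorders",
    "osteopenia": "metabolic bone disorders",
    "osteoporosis prophylaxis": "metabolic bone disorders",
    "osteopetrosis": "metabolic bone disorders",
    "bone density decreased": "metabolic bone disorders",
    "breast cancer": "breast and nipple neoplasms malignant",
    "breast cancer metastatic": "breast and nipple neoplasms malignant",
    "metastases to breast": "breast and nipple neoplasms malignant",
    "plasma cell myeloma": "plasma cell myelomas",
    "multiple myeloma": "plasma cell myelomas",
    "prostate cancer": "prostatic neoplasms malignant",
    "prostate cancer metastatic": "prostatic neoplasms malignant",
    "metastases to prostate": "prostatic neoplasms malignant",
    "metastases to bone": "metastases to specified sites",
    "metastasis": "metastases to unspecified sites",
    "metastatic neoplasm": "metastases to unspecified sites",
    "neoplasm malignant": "neoplasms malignant site unspecified"
  },
  "onj_pt_codes": [10064658, 10071014],
  "onj_pt_names": ["osteonecrosis of the jaw", "exposed bone in jaw"]
}
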