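# 15-trait schema for shallow rocky-reef benthic algae and invertebrates.
# Numbered codes are ordered scales (ordinal); lettered codes are nominal;
# yes/no traits are binary. coarse_map gives the 2-4 category coarse
# recoding used by the sensitivity analysis.
traits:
- name: morphological_form
  kind: nominal
  categories: [a, b, c, d, e, f, g, h, i, j, k, l, m]
  coarse_map: {a: flat, b: flat, c: flat, d: flat, e: flat,
               f: erect, g: erect, h: erect, m: erect,
               i: massive, j: massive, k: massive, l: massive}
- name: solitary_colonial
  kind: ordinal
  categories: ['1', '2', '3']
  coarse_map: {'1': solitary, '2': colonial, '3': colonial}
- name: maximum_longevity
  kind: ordinal
  categories: ['1', '2', '3', '4', '5', '6', '7']
  coarse_map: {'1': short, '2': short, '3': short,
               '4': medium, '5': medium, '6': long, '7': long}
- name: height
  kind: ordinal
  categories: ['1', '2', '3', '4', '5']
  coarse_map: {'1': small, '2': small, '3': medium, '4': medium, '5': large}
- name: width
  kind: ordinal
  categories: ['2', '3', '4', '5', '6']
  coarse_map: {'2': narrow, '3': narrow, '4': medium, '5': medium, '6': wide}
- name: epibiosis
  kind: nominal
  categories: ['1', '2', '3']
  coarse_map: {'1': obligate, '2': other, '3': other}
- name: energetic_resource
  kind: nominal
  categories: ['1', '2', '3']
  coarse_map: {'1': autotroph, '2': heterotroph, '3': heterotroph}
- name: photosynthetic_pigments
  kind: nominal
  categories: [a, b, c, d, e, f, h]
  coarse_map: {a: none, b: green_brown, c: green_brown, d: green_brown,
               e: red_cyano, f: red_cyano, h: mixed}
- name: feeding
  kind: nominal
  categories: [a, b, c, d, e]
  coarse_map: {a: none, b: filter, c: filter, d: filter, e: grazer}
- name: age_maturity
  kind: ordinal
  categories: ['1', '2', '3', '4', '5', '6']
  coarse_map: {'1': early, '2': early, '3': early,
               '4': late, '5': late, '6': late}
- name: asexual_reproduction
  kind: binary
  categories: ['1', '2']
  coarse_map: {'1': '1', '2': '2'}
- name: growth_rate
  kind: ordinal
  categories: ['1', '2', '3', '4', '5']
  coarse_map: {'1': slow, '2': slow, '3': moderate, '4': fast, '5': fast}
- name: calcification
  kind: nominal
  categories: [a, b, c, e, f]
  coarse_map: {a: non_calcified, b: non_calcified,
               c: calcified, e: calcified, f: calcified}
- name: chemical_defenses
  kind: binary
  categories: ['1', '2']
  coarse_map: {'1': '1', '2': '2'}
- name: mobility
  kind: binary
  categories: ['1', '2']
  coarse_map: {'1': '1', '2': '2'}
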