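- type: pm
  factors:
  - factor_id: pm_general
    weight: 1.0
    items:
    - question_id: pm_dusty_env
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_visible_dust
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_dust_freq
      map:
        never: 0.0
        sometimes: 0.5
        often: 1.0
    - question_id: pm_respirator
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_sanding
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_sweeping
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_demolition
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_outdoor_dust
      map:
        'yes': 1.0
        'no': 0.0
  - factor_id: pm_sources
    weight: 1.0
    items:
    - question_id: pm_src_silica
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_talc
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_fibers
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_wood
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_grain
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_cement
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_coal
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_asbestos
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_powder
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pm_src_weld_fume
      map:
        'yes': 1.0
        'no': 0.0
  label: Particulate Matter (PM)
- type: voc
  factors:
  - factor_id: voc_solvents
    weight: 1.0
    items:
    - question_id: voc_solvent_use
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: voc_degreasing
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: voc_paint
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: voc_glue
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: voc_freq
      map:
        never: 0.0
        sometimes: 0.5
        often: 1.0
  - factor_id: voc_fuels
    weight: 1.0
    items:
    - question_id: voc_gasoline
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: voc_printing
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: voc_drycleaning
      map:
        'yes': 1.0
        'no': 0.0
  label: Volatile Organic Compounds (VOCs)
- type: pesticides
  factors:
  - factor_id: pest_application
    weight: 1.0
    items:
    - question_id: pest_apply
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pest_mix
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pest_freq
      map:
        never: 0.0
        sometimes: 0.5
        often: 1.0
  - factor_id: pest_ambient
    weight: 1.0
    items:
    - question_id: pest_field_work
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pest_greenhouse
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: pest_fumigation
      map:
        'yes': 1.0
        'no': 0.0
  label: Pesticides
- type: metals
  factors:
  - factor_id: metal_specific
    weight: 1.0
    items:
    - question_id: met_lead
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: lead
    - question_id: met_mercury
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: mercury
    - question_id: met_cadmium
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: cadmium
    - question_id: met_arsenic
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: arsenic
    - question_id: met_iron
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: iron
    - question_id: met_welding
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: welding
    - question_id: met_other
      map:
        'yes': 1.0
        'no': 0.0
      subcomponent: other_metal
  - factor_id: metal_activities
    weight: 1.0
    items:
    - question_id: met_grinding
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: met_plating
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: met_soldering
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: met_casting
      map:
        'yes': 1.0
        'no': 0.0
  label: Metals
- type: biologicals
  factors:
  - factor_id: bio_animal
    weight: 1.0
    items:
    - question_id: bio_animals
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: bio_animal_products
      map:
        'yes': 1.0
        'no': 0.0
  - factor_id: bio_organic
    weight: 1.0
    items:
    - question_id: bio_mold
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: bio_sewage
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: bio_lab_agents
      map:
        'yes': 1.0
        'no': 0.0
  label: Biological Exposures
- type: combustion
  factors:
  - factor_id: comb_diesel
    weight: 1.0
    items:
    - question_id: comb_diesel_exhaust
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: comb_truck_bay
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: comb_freq
      map:
        never: 0.0
        sometimes: 0.5
        often: 1.0
  - factor_id: comb_other
    weight: 1.0
    items:
    - question_id: comb_fire_smoke
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: comb_furnace
      map:
        'yes': 1.0
        'no': 0.0
  label: Combustion and Diesel Exhaust
- type: electromagnetic
  factors:
  - factor_id: em_fields
    weight: 1.0
    items:
    - question_id: em_powerlines
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: em_transformers
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: em_induction
      map:
        'yes': 1.0
        'no': 0.0
  - factor_id: em_equipment
    weight: 1.0
    items:
    - question_id: em_radar
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: em_rf_equipment
      map:
        'yes': 1.0
        'no': 0.0
  label: Electromagnetic Exposure
- type: radiation
  factors:
  - factor_id: rad_ionizing
    weight: 1.0
    items:
    - question_id: rad_xray
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: rad_isotopes
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: rad_nuclear
      map:
        'yes': 1.0
        'no': 0.0
  - factor_id: rad_monitoring
    weight: 1.0
    items:
    - question_id: rad_badge
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: rad_uv
      map:
        'yes': 1.0
        'no': 0.0
  label: Radiation
- type: corrosives
  factors:
  - factor_id: corr_acids
    weight: 1.0
    items:
    - question_id: corr_acid
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: corr_caustic
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: corr_freq
      map:
        never: 0.0
        sometimes: 0.5
        often: 1.0
  - factor_id: corr_cleaning
    weight: 1.0
    items:
    - question_id: corr_industrial_clean
      map:
        'yes': 1.0
        'no': 0.0
    - question_id: corr_etching
      map:
        'yes': 1.0
        'no': 0.0
  label: Corrosives
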