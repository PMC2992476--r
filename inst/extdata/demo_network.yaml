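# Demonstration testing network: two collection sites feeding one central
# laboratory. Site A is urban (itemized SCS profile, per-location patient
# detail, ground shipment); site B is remote (aggregated entries, air
# shipment already amortized into its transport figure). All amounts are
# synthetic demonstration values in US dollars.
rounding:
  display_decimals: 2
  mode: half_up
thresholds: [5.0, 10.0]
lab:
  kit:
    tests_per_kit: 12
    kit_price: 875.0
    controls_per_run: 2
  disposables:
    - {name: specimen aliquoting, per_run: 0.40, per_specimen: 0.15}
    - {name: RNA extraction, per_run: 3.20, per_specimen: 1.07}
    - {name: PCR reaction preparation, per_run: 2.05, per_specimen: 1.06}
  labour:
    - {name: specimen receipt and processing, per_run_minutes: 49, per_specimen_minutes: 3, hourly_wage: 0.45}
    - {name: RNA extraction, per_run_minutes: 103, per_specimen_minutes: 20, hourly_wage: 0.45}
    - {name: PCR reaction preparation, per_run_minutes: 144, per_specimen_minutes: 1.5, hourly_wage: 0.45}
    - {name: results processing, per_run_minutes: 98, per_specimen_minutes: 4.8, hourly_wage: 0.45}
    - {name: administration, per_specimen_minutes: 63, hourly_wage: 0.45}
    - {name: data entry, per_specimen_minutes: 26.5, hourly_wage: 0.45}
  facilities_equipment_per_specimen: 5.62
  batch_sizes: [10, 22]
  operating_batch_size: 22
sites:
  - name: site A
    specimens_per_session: 6
    patient:
      locations:
        - {name: town centre, distance_km: 2, round_trip_fare: 0.42, lodging_nights: 0,
           nightly_rate: 0, food_cost_total: 0.81, days_away: 0.26, daily_wage: 3.50,
           patient_count: 80}
        - {name: upriver village, distance_km: 120, round_trip_fare: 8.40, lodging_nights: 1,
           nightly_rate: 4.50, food_cost_total: 5.20, days_away: 2, daily_wage: 3.60,
           patient_count: 20}
    scs:
      itemized:
        supplies:
          - {name: latex gloves, unit_cost: 0.06, units_per_specimen: 2}
          - {name: vacutainers, unit_cost: 0.12, units_per_specimen: 3}
          - {name: cold-chain thermos share, unit_cost: 0.18, units_per_specimen: 1}
        labour:
          - {name: site preparation, per_run_minutes: 20, hourly_wage: 0.45}
          - {name: registration and administration, per_specimen_minutes: 6, hourly_wage: 0.45}
          - {name: "counselling, collection, processing and packaging", per_specimen_minutes: 18, hourly_wage: 0.45}
        accommodation_per_specimen: 0.0
        shipment:
          mode: ground
          driver_labour_per_trip: 2.40
          fuel_per_trip: 6.10
          vehicle_depreciation_per_trip: 1.50
          specimens_per_shipment: 6
    delivery:
      fraction_to_scs: 0.95
      fraction_to_patient: 0.90
      mean_turnaround_days: 21
  - name: site B
    specimens_per_session: 1
    patient:
      aggregated:
        transportation: 6.64
        lodging: 2.28
        food: 3.37
        lost_income: 2.64
        total: 14.93
        median: 1.69
        min: 1.05
        max: 69.03
    scs:
      aggregated:
        supplies: 0.61
        labour: 6.66
        accommodations: 2.89
        transport: 10.76
    delivery:
      fraction_to_scs: 0.81
      fraction_to_patient: 0.99
      mean_turnaround_days: 60
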