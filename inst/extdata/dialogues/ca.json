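{
  "language": "ca",
  "menu": {
    "prompt": "Hola, sóc Wakamola {emoji:wave}! Què vols fer?\n1. Personal\n2. Dieta\n3. Activitat\n4. Wakanet (comparteix amb els teus contactes)\n5. Wakastatus (les teves puntuacions)\n6. Quant a\nRespon amb un número de l'1 al 6."
  },
  "strings": {
    "invalid_choice": "No t'he entès. Respon amb una de les opcions indicades.",
    "invalid_number": "Respon amb un número entre {min} i {max}.",
    "invalid_boolean": "Respon sí o no.",
    "section_complete": "Genial, la secció {section} està completa! {emoji:party}",
    "already_complete": "Ja has completat aquesta secció. Reinicia-la explícitament si vols canviar les respostes.",
    "assessment_complete": "Has completat totes les seccions. Consulta el teu Wakastatus des del menú!",
    "not_ready": "Completa primer les seccions Personal, Dieta i Activitat."
  },
  "sections": {
    "personal": {
      "title": "Personal",
      "questions": {
        "weight": { "prompt": "Quin és el teu pes en quilograms?" },
        "height": { "prompt": "Quina és la teva alçada en metres (p. ex. 1,75)?" },
        "gender": { "prompt": "Quin és el teu gènere? (female / male / other)" },
        "age": { "prompt": "Quants anys tens?" },
        "education_level": { "prompt": "Quin és el teu nivell d'estudis? (primary / secondary / university / postgraduate)" },
        "marital_status": { "prompt": "Quin és el teu estat civil? (single / partner / married / other)" },
        "household_size": { "prompt": "Quantes persones viuen a casa teva, incloent-te a tu?" },
        "main_activity": { "prompt": "Quina és la teva activitat principal? (study / work / other)" },
        "zip_code": { "prompt": "Quin és el teu codi postal?" },
        "sleep_hours": { "prompt": "Quantes hores dorms al dia?" },
        "cigarettes": { "prompt": "Quants cigarrets fumes al dia?" },
        "dx_hypertension": { "prompt": "T'han diagnosticat (o prens medicació per a) hipertensió? (sí/no)" },
        "dx_diabetes": { "prompt": "T'han diagnosticat (o prens medicació per a) diabetis? (sí/no)" },
        "dx_cholesterol": { "prompt": "T'han diagnosticat (o prens medicació per a) colesterol alt? (sí/no)" },
        "dx_cardiovascular": { "prompt": "T'han diagnosticat (o prens medicació per a) malaltia cardiovascular? (sí/no)" }
      }
    },
    "diet": {
      "title": "Dieta",
      "item_prompt": "Amb quina freqüència consumeixes {item}? {emoji:apple}\n1. Mai\n2. Menys d'una vegada a la setmana\n3. 1-2 vegades a la setmana\n4. 3-6 vegades a la setmana\n5. Una vegada al dia\n6. Dues o més vegades al dia"
    },
    "activity": {
      "title": "Activitat",
      "questions": {
        "vigorous_days": { "prompt": "En els darrers 7 dies, quants dies vas fer activitat física vigorosa? (0-7)" },
        "vigorous_minutes": { "prompt": "Quants minuts solies dedicar a l'activitat vigorosa en un d'aquests dies?" },
        "moderate_days": { "prompt": "En els darrers 7 dies, quants dies vas fer activitat física moderada? (0-7)" },
        "moderate_minutes": { "prompt": "Quants minuts solies dedicar a l'activitat moderada en un d'aquests dies?" },
        "walk_days": { "prompt": "En els darrers 7 dies, quants dies vas caminar almenys 10 minuts seguits? (0-7)" },
        "walk_minutes": { "prompt": "Quants minuts solies caminar en un d'aquests dies?" },
        "sitting_hours": { "prompt": "Quantes hores a la setmana passes assegut/da?" }
      }
    },
    "wakanet": {
      "title": "Wakanet",
      "intro": "Comparteix Wakamola amb els teus contactes per construir la teva xarxa {emoji:muscle}. Tens {n_contacts} contactes.",
      "invite_messages": {
        "home": "Uneix-te a Wakamola! Invitació per a les persones amb qui visc: {token}",
        "family": "Uneix-te a Wakamola! Invitació per a la meva família: {token}",
        "friend": "Uneix-te a Wakamola! Invitació per a les meves amistats: {token}",
        "work": "Uneix-te a Wakamola! Invitació per als meus companys de feina: {token}"
      }
    },
    "wakastatus": {
      "title": "Wakastatus",
      "status_message": "Aquí tens el teu estat {emoji:smile}\nWakastatus: {wakastatus}/100\nDieta (Wakalimentation): {diet_score}\nActivitat: {activity_score}\nWakaBMI: {bmi_score}\nXarxa social (Wakasocial): {social_score}\nCategoria d'IMC: {bmi_category}\nCom més alt millor: objectiu 100!"
    },
    "about": {
      "title": "Quant a"
    }
  },
  "emoji": {
    "wave": "👋",
    "party": "🎉",
    "apple": "🍎",
    "muscle": "💪",
    "smile": "🙂"
  }
}
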